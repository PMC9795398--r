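test_that("every typed table round-trips through write + read identically", {
  dir <- withr::local_tempdir()

  b <- make_businesses(c("CO", "MS", "CO"),
                       list(c("fast food", "pizza"), "diners",
                            c("pizza", "cafes", "bars")),
                       price = c(1L, NA, 3L), rating = c(4.5, 3, 5),
                       reviews = c(12L, 0L, 400L))
  write_businesses(b, file.path(dir, "businesses.csv"))
  b2 <- read_businesses(file.path(dir, "businesses.csv"))
  expect_equal(b2$business_id, b$business_id)
  expect_equal(b2$region, b$region)
  expect_equal(unclass(b2$categories), unclass(b$categories))
  expect_equal(b2$price_tier, b$price_tier)
  expect_equal(b2$rating, b$rating)
  expect_equal(b2$review_count, b$review_count)

  n <- data.frame(dish = c("fried chicken", "beet salad"),
                  calories = c(460.5, 120), serving_qty = c(100, 1),
                  serving_unit = c("g", "cup"), stringsAsFactors = FALSE)
  write_nutrition(n, file.path(dir, "nutrition.csv"))
  expect_equal(read_nutrition(file.path(dir, "nutrition.csv")), n)

  o <- data.frame(region = c("MS", "CO"), obesity_rate = c(40.8, 23.8),
                  stringsAsFactors = FALSE)
  write_obesity(o, file.path(dir, "obesity.csv"))
  o2 <- read_obesity(file.path(dir, "obesity.csv"))
  expect_equal(o2, o)
  expect_equal(nrow(o2), 2L)

  p <- data.frame(category = c("diners", "diners"), rank = 1:2,
                  dish = c("french toast", "eggs benedict"),
                  stringsAsFactors = FALSE)
  write_popular_dishes(p, file.path(dir, "popular.csv"))
  expect_equal(read_popular_dishes(file.path(dir, "popular.csv")), p,
               ignore_attr = TRUE)

  r <- data.frame(category = c("fast food", "hardware stores"),
                  is_food = c(TRUE, FALSE), stringsAsFactors = FALSE)
  write_category_registry(r, file.path(dir, "registry.csv"))
  expect_equal(read_category_registry(file.path(dir, "registry.csv")), r)
})

test_that("food-category filter keeps flagged labels, drops emptied records, and is idempotent", {
  reg <- data.frame(category = c("fast food", "pizza"),
                    is_food = c(TRUE, TRUE))
  b <- make_businesses("CO", list(c("fast food", "hardware stores"),
                                  "nail salons",
                                  c("pizza", "fast food")))
  expect_message(f <- filter_food_categories(b, reg), "excluded 1")
  expect_equal(nrow(f), 2L)
  expect_equal(f$categories[[1]], "fast food")
  expect_equal(attr(f, "n_excluded"), 1L)
  f2 <- filter_food_categories(f, reg)
  expect_equal(f2$categories, f$categories)
  expect_equal(attr(f2, "n_excluded"), 0L)

  # filtering applied at read time drops the same record
  dir <- withr::local_tempdir()
  write_businesses(b, file.path(dir, "b.csv"))
  suppressMessages(
    fb <- read_businesses(file.path(dir, "b.csv"), registry = reg))
  expect_equal(nrow(fb), 2L)
})

test_that("malformed inputs fail loudly with the offending line", {
  dir <- withr::local_tempdir()

  writeLines(c("business_id,region,categories,price_tier,rating,review_count",
               'b1,CO,"[""pizza""]",1,4.5,10',
               "b2,CO,not-json,1,4.5,10"), file.path(dir, "bad.csv"))
  expect_error(read_businesses(file.path(dir, "bad.csv")), "line 3")

  writeLines(c("business_id,region,categories,price_tier,rating,review_count",
               'b1,ZZ,"[""pizza""]",1,4.5,10'), file.path(dir, "badr.csv"))
  expect_error(read_businesses(file.path(dir, "badr.csv")),
               "unknown region code 'ZZ'")

  writeLines(c("business_id,region,categories,price_tier,rating,review_count",
               'b1,CO,"[""pizza""]",1,4.3,10'), file.path(dir, "badhalf.csv"))
  expect_error(read_businesses(file.path(dir, "badhalf.csv")), "half-step")

  writeLines(c("dish,calories,serving_qty,serving_unit", "soup,-5,100,g"),
             file.path(dir, "badn.csv"))
  expect_error(read_nutrition(file.path(dir, "badn.csv")), "calories")

  writeLines(c("region,obesity_rate", "CO,23.8", "CO,24.0"),
             file.path(dir, "bado.csv"))
  expect_error(read_obesity(file.path(dir, "bado.csv")), "duplicate region")

  expect_error(read_obesity(file.path(dir, "nope.csv")),
               class = "foodscape_missing_file")
})

test_that("empty input files yield empty typed tables with a warning", {
  dir <- withr::local_tempdir()
  writeLines("region,obesity_rate", file.path(dir, "empty.csv"))
  expect_warning(o <- read_obesity(file.path(dir, "empty.csv")), "empty")
  expect_equal(nrow(o), 0L)
  writeLines("dish,calories,serving_qty,serving_unit",
             file.path(dir, "emptyn.csv"))
  expect_warning(n <- read_nutrition(file.path(dir, "emptyn.csv")), "empty")
  expect_equal(nrow(n), 0L)
})

test_that("dish names are normalized on read", {
  dir <- withr::local_tempdir()
  writeLines(c("dish,calories,serving_qty,serving_unit",
               "  Fried   CHICKEN ,230,100,g"), file.path(dir, "n.csv"))
  expect_equal(read_nutrition(file.path(dir, "n.csv"))$dish, "fried chicken")
  expect_equal(normalize_dish("  Fried   Chicken "), "fried chicken")
})
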