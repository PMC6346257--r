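test_that("lms_zscore matches the closed form and its L -> 0 limit", {
  expect_equal(lms_zscore(80, L = 1, M = 80, S = 0.05), 0)
  expect_equal(lms_zscore(5, L = -0.3, M = 5, S = 0.1), 0)
  ## ((72/80)^1 - 1) / (1 * 0.05) = -2
  expect_equal(lms_zscore(72, L = 1, M = 80, S = 0.05), -2)
  ## limit form log(x/M)/S at x = e, M = 1, S = 1
  z_limit <- lms_zscore(exp(1), L = 1e-12, M = 1, S = 1)
  expect_equal(z_limit, 1, tolerance = 1e-9)
  ## continuous in L at 0: tiny-but-finite L agrees with the limit form
  expect_equal(lms_zscore(exp(1), L = 1e-6, M = 1, S = 1), z_limit,
               tolerance = 1e-5)
  expect_error(lms_zscore(-1, 1, 80, 0.05), "positive")
  expect_error(lms_zscore(70, 1, -80, 0.05), "positive")
  expect_error(lms_zscore(70, 1, 80, 0), "positive")
})

test_that("lms_zscore is strictly increasing in x and inverts exactly", {
  set.seed(31)
  for (i in 1:25) {
    L <- runif(1, -1, 1.5); M <- runif(1, 2, 120); S <- runif(1, 0.03, 0.2)
    x <- sort(runif(50, 0.6 * M, 1.6 * M))
    z <- lms_zscore(x, L, M, S)
    expect_true(all(diff(z) > 0))
    ## round trip through the algebraic inverse
    z0 <- runif(10, -3.5, 3.5)
    x0 <- cgfmap:::lms_inverse(z0, L, M, S)
    expect_equal(lms_zscore(x0, L, M, S), z0, tolerance = 1e-10)
  }
})

test_that("growth failure classification is strict at the threshold", {
  expect_true(classify_cgf(-2.5))
  expect_false(classify_cgf(-2.0))
  expect_false(classify_cgf(0))
  expect_error(classify_cgf(NaN), "finite")
  ## afflicted count is nonincreasing as the threshold decreases
  set.seed(5)
  z <- rnorm(500, -1.5, 1.2)
  counts <- vapply(c(-1, -1.5, -2, -2.5, -3),
                   function(th) sum(classify_cgf(z, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("synthetic LMS tables are valid and the CSV loader round-trips", {
  for (ind in c("HAZ", "WHZ", "WAZ")) {
    tab <- synthetic_lms_table(ind)
    expect_true(all(tab$M > 0), info = ind)
    expect_true(all(tab$S > 0), info = ind)
    expect_setequal(unique(tab$sex), c("male", "female"))
  }
  tab <- synthetic_lms_table("HAZ")
  tf <- tempfile(fileext = ".csv")
  write.csv(tab, tf, row.names = FALSE)
  tab2 <- read_lms_table(tf)
  expect_equal(tab2$M, tab$M)
  expect_error(cgfmap:::lms_lookup(tab, "HAZ", "male", 600), "stratum")
})

test_that("exclusion rules drop the right records and are idempotent", {
  rec <- data.frame(
    cluster_id = c(1, 1, 2, 3, 4),
    sex = c("male", NA, "female", "male", "female"),
    age = c(10, 20, NA, 30, 24),
    height = c(80, 85, 75, 90, 82), weight = NA_real_,
    interview_year = 2010, interview_month = 5, survey_weight = 1)
  meta <- data.frame(cluster_id = 1:4, polygon_id = c(NA, NA, 7L, 8L),
                     N = c(2L, 5L, 1L, 1L))
  out <- apply_exclusions(rec, cluster_meta = meta)
  lg <- setNames(out$log$n_excluded, out$log$rule)
  expect_equal(unname(lg["missing_sex"]), 1L)
  expect_equal(unname(lg["missing_age"]), 1L)
  ## clusters 3 and 4 are polygons with N = 1
  expect_equal(unname(lg["polygon_n1"]), 2L)
  expect_equal(nrow(out$records), 1L)
  ## idempotence: a second pass excludes nothing
  out2 <- apply_exclusions(out$records, cluster_meta = meta)
  expect_equal(sum(out2$log$n_excluded), 0L)
  expect_equal(out2$records, out$records)
})

test_that("collapse counts scoreable children strictly below the threshold", {
  tab <- synthetic_lms_table("HAZ")
  mk <- function(z, cluster, age = 24, sex = "male") {
    p <- cgfmap:::lms_lookup(tab, "HAZ", sex, age)
    data.frame(cluster_id = cluster, sex = sex, age = age,
               height = cgfmap:::lms_inverse(z, p$L, p$M, p$S),
               weight = NA_real_, interview_year = 2008, interview_month = 3)
  }
  rec <- rbind(mk(-2.5, 1), mk(-1.0, 1), mk(-3.0, 1),
               mk(-2.0, 2), mk(-2.0, 2))
  out <- collapse_to_cluster(rec, tab, "stunting")
  expect_equal(out$N, c(3L, 2L))
  expect_equal(out$C, c(2L, 0L))   # exactly -2 does not count
  expect_equal(out$month, c(3L, 3L))
  ## cluster with no scoreable children is omitted
  rec2 <- rbind(rec, data.frame(cluster_id = 3, sex = "male", age = 24,
                                height = NA_real_, weight = NA_real_,
                                interview_year = 2008, interview_month = 3))
  out2 <- collapse_to_cluster(rec2, tab, "stunting")
  expect_setequal(out2$cluster_id, c(1, 2))
})

test_that("cluster_obs validation enforces the geometry and count contracts", {
  expect_error(as_cluster_obs(data.frame(cluster_id = 1, year = 2000, N = 0,
                                         C = 0, weight = 1)), "N >= 1")
  expect_error(as_cluster_obs(data.frame(cluster_id = 1, year = 2000, N = 5,
                                         C = 6, weight = 1)), "C <= N")
  ## both point and polygon set
  expect_error(as_cluster_obs(data.frame(cluster_id = 1, year = 2000, N = 5,
                                         C = 1, weight = 1, x = 1, y = 1,
                                         polygon_id = 3L)), "exactly one")
})
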