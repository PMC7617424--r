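test_that("suture maps parse with region normalization and hard errors", {
  map <- tiny_map()
  expect_s3_class(map, "suture_map")
  expect_equal(map$region, 1:6)
  expect_equal(map$region_name[2], "cranial base")

  # region given as synonym or ordinal
  p <- write_matrix_csv(c("suture,region,origin",
                          "a,palatal,mesoderm", "b,3,boundary"))
  m2 <- read_suture_map(p)
  expect_equal(m2$region, c(4L, 3L))

  p_bad <- write_matrix_csv(c("suture,region,origin", "a,orbital,mesoderm"))
  expect_error(read_suture_map(p_bad), "unknown Krogman region 'orbital'")
  p_dup <- write_matrix_csv(c("suture,region,origin",
                              "a,vault,mesoderm", "a,facial,mesoderm"))
  expect_error(read_suture_map(p_dup), "duplicate")
})

test_that("the bundled suture map has 31 sutures spanning all 6 regions", {
  map <- krogman_sutures()
  expect_equal(nrow(map), 31L)
  expect_setequal(unique(map$region), 1:6)
  expect_true(all(map$origin %in% c("neural_crest", "mesoderm", "boundary")))
  expect_false(anyDuplicated(map$suture) > 0)
})

test_that("score matrices parse, flag bad cells with coordinates, round-trip", {
  map <- tiny_map()
  p <- write_matrix_csv(c("specimen_id,interfrontal,basispheno-presphenoid",
                          "s1,1,5", "s2,?,3"))
  m <- read_score_matrix(p, map)
  expect_s3_class(m, "fusion_matrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(m["s2", "interfrontal"]))
  expect_equal(sum(is.na(m)), 1L)

  p6 <- write_matrix_csv(c("specimen_id,interfrontal", "s1,6"))
  expect_error(read_score_matrix(p6, map), "row 1 's1', column 'interfrontal'")

  p0 <- write_matrix_csv("specimen_id,interfrontal")
  expect_error(read_score_matrix(p0, map), "no specimens")

  pu <- write_matrix_csv(c("specimen_id,unknown-suture", "s1,2"))
  expect_error(read_score_matrix(pu, map), "not present in suture map")

  # write -> read is lossless, including the '?' token
  out <- withr::local_tempfile(fileext = ".csv")
  write_score_matrix(m, out)
  expect_equal(unclass(read_score_matrix(out, map)), unclass(m))
})

test_that("columns are harmonized to suture-map order", {
  map <- tiny_map()
  p <- write_matrix_csv(c("specimen_id,internasal,interfrontal",
                          "s1,2,4"))
  m <- read_score_matrix(p, map)
  expect_equal(colnames(m), c("interfrontal", "internasal"))
  expect_equal(as.integer(m["s1", ]), c(4L, 2L))
})

test_that("absent-bone rule sets cells to 1, flags overrides, is idempotent", {
  mat <- make_matrix(list(s1 = c(NA, 4L), s2 = c(2L, 1L)),
                     c("maxillo-jugal", "jugo-squamosal"))
  ab <- data.frame(specimen = c("s1", "s1"),
                   suture = c("maxillo-jugal", "jugo-squamosal"))
  out <- apply_absent_bone_rule(mat, ab)
  expect_equal(as.integer(out["s1", ]), c(1L, 1L))
  expect_equal(as.integer(out["s2", ]), c(2L, 1L))   # untouched
  ov <- attr(out, "absent_overrides")
  expect_equal(nrow(ov), 1L)                         # the prior 4 only
  expect_equal(ov$prior_score, 4L)

  # idempotent on cell values; empty absence set is the identity
  again <- apply_absent_bone_rule(out, ab)
  expect_equal(unclass(again)[, ], unclass(out)[, ])
  expect_identical(apply_absent_bone_rule(mat, ab[0, ]), mat)

  expect_error(apply_absent_bone_rule(mat,
                                      data.frame(specimen = "sX",
                                                 suture = "maxillo-jugal")),
               "not in matrix")
})

test_that("interpolation fills interior gaps, rounds toward open, reports ends", {
  sut <- c("a", "b", "c")
  map_lines <- c("suture,region,origin", "a,vault,mesoderm",
                 "b,vault,mesoderm", "c,vault,mesoderm")
  # one species, three specimens young -> old
  mat <- make_matrix(list(y = c(2L, 3L, 2L),
                          m = c(NA, NA, NA),
                          o = c(4L, 3L, 3L)), sut)
  ord <- list(sp = c("y", "m", "o"))
  out <- interpolate_unknowns(mat, ord)
  expect_equal(as.integer(out["m", ]), c(3L, 3L, 2L))  # (2,?,4)->3; (3,?,3)->3; (2,?,3)->2
  expect_equal(nrow(attr(out, "unfilled")), 0L)

  # runs of missing share the flanking pair; series-end missing is reported
  mat2 <- make_matrix(list(a = c(2L), b = c(NA), c = c(NA), d = c(4L),
                           e = c(NA)), "a")
  out2 <- interpolate_unknowns(mat2, list(sp = c("a", "b", "c", "d", "e")))
  expect_equal(as.integer(out2[, "a"]), c(2L, 3L, 3L, 4L, NA))
  expect_equal(attr(out2, "unfilled")$specimen, "e")
})

test_that("interpolation never alters known cells and stays in 1..5", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    v <- sample(1:5, n, replace = TRUE)
    vm <- v
    vm[sample(n, sample(0:(n - 2), 1))] <- NA
    mat <- fusion_matrix(matrix(vm, ncol = 1,
                                dimnames = list(paste0("s", 1:n), "x")))
    out <- interpolate_unknowns(mat, list(sp = paste0("s", 1:n)))
    known <- !is.na(vm)
    expect_equal(as.integer(out[known, 1]), vm[known])
    filled <- out[!is.na(out[, 1]), 1]
    expect_true(all(filled >= 1 & filled <= 5))
    # no interior missing remains
    idx <- which(is.na(out[, 1]))
    if (length(idx)) {
      kn <- which(!is.na(vm))
      expect_true(all(idx < min(kn) | idx > max(kn)))
    }
  }
})

test_that("validation reports issues without modifying data", {
  map <- tiny_map()
  mat <- make_matrix(list(s1 = c(1L, 2L), s2 = c(3L, 3L), s3 = c(2L, 5L),
                          lone = c(1L, 1L)),
                     c("interfrontal", "basispheno-presphenoid"))
  meta <- data.frame(specimen_id = c("s1", "s2", "s3", "lone"),
                     species = c("sp", "sp", "sp", "other"),
                     stage = c("F", "I", "A", "A"),
                     centroid_size = c(10, 20, 30, 5))
  rep <- validate_dataset(mat, map, meta)
  expect_s3_class(rep, "validation_report")
  # s1->s2->s3 on suture 1 is 1,3,2: one decrease
  expect_equal(rep$monotonicity_violations$suture, "interfrontal")
  expect_equal(rep$small_species, "other")
  expect_equal(length(rep$specimens_without_metadata), 0L)
  expect_equal(nrow(rep$residual_missing), 0L)

  # clean dataset -> no issues
  mat2 <- make_matrix(list(s1 = c(1L, 1L), s2 = c(2L, 3L)),
                      c("interfrontal", "basispheno-presphenoid"))
  meta2 <- meta[1:2, ]
  rep2 <- validate_dataset(mat2, map, meta2)
  expect_equal(rep2$n_issues, 0L)
})
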