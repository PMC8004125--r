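test_that("VIA writer/reader round-trips vertex lists exactly", {
  path <- tempfile(fileext = ".json")
  anns <- list(
    list(frame_id = "frame_001_bmode.png",
         vertices = matrix(c(10.5, 10, 40, 10.25, 25, 40), ncol = 2,
                           byrow = TRUE, dimnames = list(NULL, c("x", "y")))),
    list(frame_id = "frame_002_bmode.png",
         vertices = matrix(c(0, 0, 100, 0, 100, 80, 0, 80), ncol = 2,
                           byrow = TRUE, dimnames = list(NULL, c("x", "y")))))
  write_via_annotations(anns, path)
  back <- read_via_annotations(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$frame_id, anns[[i]]$frame_id)
    expect_identical(unname(back[[i]]$vertices), unname(anns[[i]]$vertices))
  }
})

test_that("VIA reader handles empty and malformed files", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(project = list(pid = "x"), file = list(),
                            metadata = list()), path, auto_unbox = TRUE)
  expect_length(read_via_annotations(path), 0)

  # triangle -> one annotation with 3 vertices
  tri <- list(list(frame_id = "f.png",
                   vertices = matrix(c(10, 10, 40, 10, 25, 40), ncol = 2,
                                     byrow = TRUE)))
  write_via_annotations(tri, path)
  got <- read_via_annotations(path)
  expect_length(got, 1)
  expect_identical(nrow(got[[1]]$vertices), 3L)

  # non-polygon region (VIA rectangle, shape code 2) is rejected
  bad <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bad$metadata[[1]]$xy <- c(2, 1, 1, 5, 5)
  jsonlite::write_json(bad, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_via_annotations(path), "not a polygon")

  writeLines("{not json", path)
  expect_error(read_via_annotations(path), "parseable")
})

test_that("polygon rasterization agrees with the point-in-polygon oracle", {
  set.seed(21)
  for (rep in 1:3) {
    nv <- sample(3:7, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    verts <- cbind(x = 10 + 6 * cos(ang) * runif(nv, 0.6, 1.4),
                   y = 9 + 6 * sin(ang) * runif(nv, 0.6, 1.4))
    m <- polygon_mask(verts, 20, 22)
    for (r in seq_len(20)) for (cc in seq_len(22)) {
      expect_identical(m[r, cc],
                       oracle_point_in_polygon(cc - 1, r - 1, verts),
                       info = sprintf("rep %d pixel (%d,%d)", rep, r, cc))
    }
  }
})

test_that("patch extraction applies the strict 2601/0 labeling rule", {
  p <- synthetic_params(seed = 6, n_per_class = 1)
  st <- generate_annotated_study(p, frame_size = 360, n_frames = 1, seed = 2)
  frame <- st$frames[[1]]

  # polygon covering the entire frame: every candidate is HCC at 2601
  big <- cbind(x = c(-1, 360, 360, -1), y = c(-1, -1, 360, 360))
  pp <- extract_patches(frame, big)
  expect_identical(length(pp), 16L)
  expect_true(all(pp$label == "HCC"))
  expect_true(all(attr(pp, "intersection") == 51^2))

  # polygon enclosing no pixel center: every candidate has intersection 0
  far <- cbind(x = c(10.2, 10.8, 10.5), y = c(10.2, 10.2, 10.8))
  pp0 <- extract_patches(frame, far)
  expect_true(all(pp0$label == "PAR"))
  expect_true(all(attr(pp0, "intersection") == 0))
  expect_identical(length(pp0), 16L)

  # degenerate polygon
  expect_error(extract_patches(frame, cbind(x = c(1, 2, 3), y = c(1, 2, 3))),
               "degenerate")
})

test_that("candidate patches tile the search region disjointly", {
  p <- synthetic_params(seed = 6, n_per_class = 1)
  st <- generate_annotated_study(p, frame_size = 360, n_frames = 1, seed = 2)
  pp <- extract_patches(st$frames[[1]], st$polygons[[1]])
  org <- pp$origin
  # all emitted patches lie on the 51-stride grid anchored at one corner
  expect_true(all(diff(sort(unique(org$row))) %% 51 == 0))
  expect_true(all(diff(sort(unique(org$col))) %% 51 == 0))
  # pairwise disjoint in pixel space
  if (length(pp) > 1) {
    for (i in seq_len(length(pp) - 1)) for (j in (i + 1):length(pp)) {
      overlap_r <- max(0, min(org$row[i], org$row[j]) + 51 -
                         max(org$row[i], org$row[j]))
      overlap_c <- max(0, min(org$col[i], org$col[j]) + 51 -
                         max(org$col[i], org$col[j]))
      expect_true(overlap_r == 0 || overlap_c == 0)
    }
  }
  # every emitted intersection is exactly 0 or 2601, never in between
  expect_true(all(attr(pp, "intersection") %in% c(0L, 51L^2)))
  # and on a centered blob both classes plus discarded partial tiles exist
  expect_setequal(as.character(unique(pp$label)), c("HCC", "PAR"))
  expect_lt(length(pp), 16L)  # some of the 16 candidates were partial
})

test_that("rotation augmentation quadruples counts and preserves content", {
  d <- generate_paired_patches(synthetic_params(seed = 8, n_per_class = 3))
  aug <- augment_rotations(d)
  expect_identical(length(aug), 4L * length(d))
  expect_identical(as.character(aug$label),
                   rep(as.character(d$label), 4))
  expect_setequal(unique(aug$augmentation),
                  c("none", "rot90", "rot180", "rot270"))
  # rot180 twice is the identity
  r180 <- function(m) ceusfuse:::rot90cw(ceusfuse:::rot90cw(m))
  m <- d$bmode[, , 1]
  expect_identical(r180(r180(m)), m)
  # rot90 equals an independent coordinate-remapping oracle on a 5x5 array
  set.seed(1)
  a <- matrix(rnorm(25), 5, 5)
  expected <- matrix(0, 5, 5)
  for (r in 1:5) for (cc in 1:5) expected[cc, 5 + 1 - r] <- a[r, cc]
  expect_equal(ceusfuse:::rot90cw(a), expected)
  # both channels rotated identically
  n <- length(d)
  expect_identical(aug$bmode[, , n + 1], ceusfuse:::rot90cw(d$bmode[, , 1]))
  expect_identical(aug$ceus[, , n + 1], ceusfuse:::rot90cw(d$ceus[, , 1]))
})

test_that("train-time augmentation has identity elements and valid moves", {
  m <- matrix(seq_len(30), 5, 6)
  # zero translation and no flip leave the patch untouched
  expect_identical(ceusfuse:::translate_reflect(m, 0, 0), m)
  # horizontal flip twice is the identity
  fh <- m[, ncol(m):1]
  expect_identical(fh[, ncol(m):1], m)
  # translation by (2, 3) matches an index-arithmetic shift oracle with
  # reflected border (no edge duplication) on a ramp image
  ramp <- outer(1:8, 1:9, function(r, cc) 10 * r + cc)
  got <- ceusfuse:::translate_reflect(ramp, 2, 3)
  refl <- function(i, n) { i <- ifelse(i < 1, 2 - i, i); ifelse(i > n, 2 * n - i, i) }
  expected <- matrix(0, 8, 9)
  for (r in 1:8) for (cc in 1:9)
    expected[r, cc] <- ramp[refl(r - 2, 8), refl(cc - 3, 9)]
  expect_identical(got, expected)
  # collection-level contract: labels and shapes preserved, channels moved
  # identically
  d <- generate_paired_patches(synthetic_params(seed = 9, n_per_class = 4))
  set.seed(11)
  a <- train_time_augment(d)
  expect_identical(length(a), length(d))
  expect_identical(a$label, d$label)
  expect_identical(dim(a$bmode), dim(d$bmode))
  set.seed(11)
  b <- train_time_augment(d)
  expect_identical(a$bmode, b$bmode)  # seeded reproducibility
})
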