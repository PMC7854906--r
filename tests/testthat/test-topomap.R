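proj61 <- azimuthal_project(packaged_montage())

test_that("Clough-Tocher rendering reproduces constant and linear fields", {
  op <- topomap_operator(proj61$pos2d, resolution = 32)
  # constants
  img <- render_topomap(rep(3.25, 61), op = op)
  expect_lt(max(abs(img - 3.25)[op$mask]), 1e-9)
  # linear field 2x - y + 0.5 (oracle: direct evaluation on the grid)
  vals <- 2 * proj61$pos2d[, 1] - proj61$pos2d[, 2] + 0.5
  img <- render_topomap(vals, op = op)
  gx <- seq(op$extent["xmin"], op$extent["xmax"], length.out = 32)
  gy <- seq(op$extent["ymax"], op$extent["ymin"], length.out = 32)
  truth <- outer(gy, gx, function(y, x) 2 * x - y + 0.5)
  expect_lt(max(abs(img - truth)[op$mask]), 1e-6)
  # fill contract
  img0 <- render_topomap(vals, op = op, fill = 0)
  expect_true(all(img0[!op$mask] == 0))
})

test_that("interpolation is C1: second differences shrink quadratically", {
  set.seed(4)
  vals <- rnorm(61)
  d2q <- function(res) {
    op <- topomap_operator(proj61$pos2d, resolution = res)
    img <- render_topomap(vals, op = op)
    # interior pixels whose full 3x3 neighborhood is inside the hull
    ok <- op$mask
    core <- ok[2:(res - 1), 2:(res - 1)] &
      ok[1:(res - 2), 2:(res - 1)] & ok[3:res, 2:(res - 1)] &
      ok[2:(res - 1), 1:(res - 2)] & ok[2:(res - 1), 3:res]
    dr <- img[1:(res - 2), 2:(res - 1)] - 2 * img[2:(res - 1), 2:(res - 1)] +
      img[3:res, 2:(res - 1)]
    dc <- img[2:(res - 1), 1:(res - 2)] - 2 * img[2:(res - 1), 2:(res - 1)] +
      img[2:(res - 1), 3:res]
    quantile(abs(c(dr[core], dc[core])), 0.99)
  }
  # a C0-only surface would only halve its second differences when the
  # grid is refined; a C1 surface quarters them (0.99 quantile keeps the
  # pre-asymptotic vertex neighborhoods from dominating)
  expect_gt(d2q(48) / d2q(96), 3)
})

test_that("rendering is equivariant to consistent channel permutations", {
  set.seed(11)
  vals <- rnorm(61)
  perm <- sample(61)
  img1 <- render_topomap(vals, pos2d = proj61$pos2d, resolution = 24)
  img2 <- render_topomap(vals[perm], pos2d = proj61$pos2d[perm, ],
                         resolution = 24)
  expect_equal(img1, img2, tolerance = 1e-10)
})

test_that("degenerate layouts are rejected", {
  line <- cbind(seq(0, 1, length.out = 6), seq(0, 2, length.out = 6))
  expect_error(topomap_operator(line, resolution = 8), "collinear")
  expect_error(topomap_operator(proj61$pos2d[1:3, ], 8), "at least 4")
})

test_that("image stacks follow the 32 x 32 x 5 contract and determinism", {
  set.seed(2)
  spec <- synthetic_spec(n_channels = 61, fs = 128, duration_s = 4,
                         n_trials = 1, classes = list(1, 1), seed = 2)
  gen <- generate_synthetic_eeg(spec)
  de <- extract_de_features(synthetic_epochs(gen))
  st <- render_image_stack(de, gen$montage)
  expect_equal(dim(st$images), c(dim(de$values)[1], 32L, 32L, 5L))
  # identical feature rows render identically
  de2 <- de
  de2$values[2, , ] <- de2$values[1, , ]
  st2 <- render_image_stack(de2, gen$montage)
  expect_identical(st2$images[1, , , ], st2$images[2, , , ])
  # channel mismatch errors name the offenders
  de3 <- de
  de3$channel_names[1] <- "NOPE"
  expect_error(render_image_stack(de3, gen$montage), "NOPE")
})

test_that("min-max standardization maps scoped groups onto [0, 1]", {
  # hand-built stack: one window, 2x2 grid with 3 in-hull pixels
  mk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  imgs <- array(0, c(1, 2, 2, 1))
  imgs[1, , , 1] <- matrix(c(2, 4, 6, 0), 2, 2)
  x <- structure(list(images = imgs, resolution = 2L, mask = mk, fill = 0,
                      labels = 1L, domains = 1L, bands = list(),
                      normalized = FALSE),
                 class = "topo_images")
  out <- minmax_standardize(x)
  expect_equal(sort(out$images[1, , , 1][mk]), c(0, 0.5, 1))
  expect_equal(out$images[1, , , 1][!mk], 0)
  # degenerate constant group maps to zero
  x$images[1, , , 1] <- matrix(c(5, 5, 5, 0), 2, 2)
  expect_true(all(minmax_standardize(x)$images[1, , , 1][mk] == 0))
  # idempotence and range contract on real images
  spec <- synthetic_spec(n_channels = 16, fs = 128, duration_s = 4,
                         n_trials = 1, classes = list(1, 1), seed = 3)
  gen <- generate_synthetic_eeg(spec)
  st <- render_image_stack(extract_de_features(synthetic_epochs(gen)),
                           gen$montage)
  for (scope in c("per_image_band", "per_band_global")) {
    n1 <- minmax_standardize(st, scope = scope)
    expect_true(all(n1$images >= 0 & n1$images <= 1))
    n2 <- minmax_standardize(n1, scope = scope)
    expect_equal(n1$images, n2$images, tolerance = 1e-12)
  }
  # per-image-band scope: every slice spans [0, 1] exactly
  n1 <- minmax_standardize(st)
  d <- dim(n1$images)
  flat <- array(n1$images, c(d[1], d[2] * d[3], d[4]))[, as.vector(st$mask), ]
  expect_equal(range(apply(flat, c(1, 3), max)), c(1, 1), tolerance = 1e-12)
  expect_equal(range(apply(flat, c(1, 3), min)), c(0, 0), tolerance = 1e-12)
})
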