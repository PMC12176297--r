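# Hand-built label arrays exercising the assignment rules.
toy_foci <- function(labels, spacing = c(0.2, 0.1, 0.1)) {
  tab <- xiquant:::.measure_labels(labels, spacing)
  tab$assigned_nucleus <- NA_integer_
  structure(list(table = tab, labels = labels, spacing = spacing,
                 threshold = 0), class = "xi_foci")
}
toy_nuclei <- function(labels, spacing = c(0.2, 0.1, 0.1)) {
  tab <- xiquant:::.measure_labels(labels, spacing)
  tab$integrated_intensity <- NULL
  tab$touches_xy_edge <- FALSE
  structure(list(table = tab, labels = labels, spacing = spacing,
                 n_removed_edge = 0L, n_removed_small = 0L),
            class = "xi_nuclei")
}

test_that("a focus fully inside one nucleus is assigned to it", {
  nl <- array(0L, c(4, 6, 6)); nl[2:3, 2:5, 2:5] <- 1L
  fl <- array(0L, c(4, 6, 6)); fl[2, 3:4, 3:4] <- 1L
  foc <- assign_foci(toy_foci(fl), toy_nuclei(nl))
  expect_equal(foc$table$assigned_nucleus, 1L)
})

test_that("max-overlap rule beats partial overlap; ties go to lower label", {
  nl <- array(0L, c(1, 10, 10))
  nl[1, 1:5, ] <- 1L
  nl[1, 7:10, ] <- 2L
  # focus overlapping nucleus 1 by 10 voxels, nucleus 2 by 3
  fl <- array(0L, c(1, 10, 10))
  fl[1, 4:5, 1:5] <- 1L       # 10 voxels in nucleus 1
  fl[1, 7, 1:3] <- 1L         # 3 voxels in nucleus 2
  foc <- assign_foci(toy_foci(fl), toy_nuclei(nl))
  expect_equal(foc$table$assigned_nucleus, 1L)
  # exact tie: 2 voxels in each -> smaller nucleus label
  fl2 <- array(0L, c(1, 10, 10))
  fl2[1, 5, 1:2] <- 1L
  fl2[1, 7, 1:2] <- 1L
  foc2 <- assign_foci(toy_foci(fl2), toy_nuclei(nl))
  expect_equal(foc2$table$assigned_nucleus, 1L)
})

test_that("zero overlap leaves a focus unassigned", {
  nl <- array(0L, c(2, 6, 6)); nl[1, 1:2, 1:2] <- 1L
  fl <- array(0L, c(2, 6, 6)); fl[2, 5:6, 5:6] <- 1L
  foc <- assign_foci(toy_foci(fl), toy_nuclei(nl))
  expect_true(is.na(foc$table$assigned_nucleus))
})

test_that("mismatched stack shapes are an error", {
  nl <- array(0L, c(2, 6, 6)); nl[1, 1, 1] <- 1L
  fl <- array(0L, c(2, 6, 7)); fl[1, 1, 1] <- 1L
  expect_error(assign_foci(toy_foci(fl), toy_nuclei(nl)), "shape")
})

test_that("random 5x5x5 labelings match a per-voxel brute-force tally", {
  set.seed(17)
  for (rep in 1:20) {
    nl <- array(sample(0:3, 125, replace = TRUE), c(5, 5, 5))
    fl <- array(0L, c(5, 5, 5))
    # a few random connected-ish foci blobs
    nf <- sample(1:4, 1)
    for (f in seq_len(nf)) {
      ctr <- sample(1:5, 3, replace = TRUE)
      zz <- max(1, ctr[1] - 1):min(5, ctr[1] + 1)
      fl[zz, ctr[2], ctr[3]] <- f
    }
    foc <- assign_foci(toy_foci(fl), toy_nuclei(nl))
    for (f in sort(unique(fl[fl > 0]))) {
      ov <- integer(3)
      for (n in 1:3) ov[n] <- sum(fl == f & nl == n)
      expected <- if (all(ov == 0)) NA_integer_ else which.max(ov)
      got <- foc$table$assigned_nucleus[foc$table$label == f]
      expect_equal(got, as.integer(expected))
    }
  }
})

test_that("per-nucleus summaries match a brute-force group-by", {
  set.seed(23)
  nl <- array(0L, c(6, 20, 20))
  nl[2:5, 2:9, 2:9] <- 1L
  nl[2:5, 12:19, 12:19] <- 2L
  fl <- array(0L, c(6, 20, 20))
  fl[3, 3:4, 3] <- 1L
  fl[4, 5, 5:6] <- 2L
  fl[3, 14, 14] <- 3L
  fl[2, 1, 1] <- 4L  # outside both nuclei
  foc <- assign_foci(toy_foci(fl), toy_nuclei(nl),
                     seg_params(min_focus_volume_vox = 1))
  sm <- summarize_nuclei(toy_nuclei(nl), foc)
  expect_equal(sm$n_foci[sm$nucleus == 1], 2L)
  expect_equal(sm$n_foci[sm$nucleus == 2], 1L)
  expect_equal(attr(sm, "n_unassigned"), 1L)
  # nucleus 2 has one focus: no nearest-neighbour distance
  expect_true(is.na(sm$mean_nn_um[sm$nucleus == 2]))
  expect_false(is.na(sm$mean_nn_um[sm$nucleus == 1]))
})

test_that("batch_process pools per-nucleus rows and logs failures", {
  pars <- image_sim_params(stack_shape = c(24L, 160L, 160L), n_nuclei = 1L,
                           nucleus_radii = list(axial = c(1.7, 1.9),
                                                lateral = c(3.2, 3.6)))
  sim <- sim_image_population(pars, 2, seed = 41)
  manifest <- data.frame(image_id = c("img1", "img2"),
                         genotype = "wt", replicate = "r1",
                         dapi_channel = 1L, fish_channel = 2L)
  manifest$stack <- sim$stacks
  out <- batch_process(manifest)
  expect_equal(nrow(out), 2L)
  expect_equal(out$image_id, c("img1", "img2"))
  expect_true(all(out$genotype == "wt"))
  expect_equal(attr(out, "log")$status, c("ok", "ok"))

  # unreadable path is logged and skipped with a warning
  tmp <- tempfile(fileext = ".tif")
  write_image_stack(sim$stacks[[1]], tmp)
  manifest3 <- data.frame(image_id = c("good", "bad"),
                          genotype = "wt", replicate = "r1",
                          dapi_channel = 1L, fish_channel = 2L,
                          path = c(tmp, "/nonexistent/file.tif"))
  w <- capture_warnings(out3 <- batch_process(manifest3))
  expect_true(any(grepl("skipped", w)))
  lg <- attr(out3, "log")
  expect_equal(lg$status, c("ok", "error"))
  expect_true(all(out3$image_id == "good"))
})

test_that("an empty manifest gives an empty table and a warning", {
  expect_warning(out <- batch_process(data.frame()), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("TIFF round trip preserves voxels, spacing and channel names", {
  pars <- image_sim_params(stack_shape = c(8L, 48L, 48L), n_nuclei = 0L)
  sim <- sim_image_population(pars, 1, seed = 5)
  st <- sim$stacks[[1]]
  tmp <- tempfile(fileext = ".tif")
  write_image_stack(st, tmp)
  back <- read_image_stack(tmp)
  expect_equal(back$voxels, st$voxels)
  expect_equal(back$spacing, st$spacing)
  expect_equal(back$channel_names, st$channel_names)
})
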