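# frame with oxygens at given positions (hydrogens tag along rigidly)
frame_with_oxygens <- function(o, box = NULL) {
  sites <- hydroinfo:::.water_sites(water_models("SPC")$SPC)
  coords <- do.call(rbind, lapply(seq_len(nrow(o)), function(i) {
    sweep(sites, 2, o[i, ], "+")
  }))
  water_frame(coords, molecule = rep(seq_len(nrow(o)), each = 3),
              elements = rep(c("O", "H", "H"), nrow(o)), box = box)
}

test_that("transitive linkage merges chains; tight cutoffs split them", {
  fr <- frame_with_oxygens(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  cs <- sevick_clusters(fr, r_cut = 3.5)
  expect_equal(length(cs$sizes), 1)
  expect_equal(cs$sizes, 3L)
  cs2 <- sevick_clusters(fr, r_cut = 2.5)
  expect_equal(sort(cs2$sizes), c(1L, 1L, 1L))
  # single molecule
  fr1 <- frame_with_oxygens(rbind(c(0, 0, 0)))
  expect_equal(sevick_clusters(fr1, 3.5)$sizes, 1L)
  # coincident oxygens are linked at distance zero
  fr0 <- frame_with_oxygens(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(sevick_clusters(fr0, 3.5)$sizes, 2L)
})

test_that("minimum-image convention links molecules across the box", {
  fr <- frame_with_oxygens(rbind(c(0.5, 5, 5), c(9.5, 5, 5)),
                           box = c(10, 10, 10))
  expect_equal(sevick_clusters(fr, r_cut = 1.5)$sizes, 2L)
  fr_open <- frame_with_oxygens(rbind(c(0.5, 5, 5), c(9.5, 5, 5)))
  expect_equal(sort(sevick_clusters(fr_open, r_cut = 1.5)$sizes), c(1L, 1L))
})

test_that("implementation equals the brute-force oracle on random frames", {
  for (seed in 1:30) {
    n <- 2 + (seed %% 12)
    box <- if (seed %% 3 == 0) c(8, 9, 10) else NULL
    fr <- random_water_frame(n, edge = 8, seed = seed, box = box)
    r_cut <- runif(1, 2, 5)
    got <- sevick_clusters(fr, r_cut)
    want <- brute_force_clusters(fr, r_cut)
    expect_equal(sort(got$sizes), sort(want$sizes))
    # same partition up to label permutation
    expect_equal(length(unique(paste(got$cluster, want$cluster))),
                 length(unique(got$cluster)))
  }
})

test_that("shrinking the cutoff only refines the partition", {
  for (seed in 1:10) {
    fr <- random_water_frame(10, edge = 9, seed = seed + 100)
    big <- sevick_clusters(fr, 4.0)$cluster
    small <- sevick_clusters(fr, 2.8)$cluster
    # every small-cutoff cluster must sit inside one big-cutoff cluster
    for (cl in unique(small)) {
      expect_equal(length(unique(big[small == cl])), 1)
    }
  }
})

test_that("molecule permutation permutes labels, not the size multiset", {
  o <- rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0), c(13, 0, 0))
  fr <- frame_with_oxygens(o)
  fr_perm <- frame_with_oxygens(o[c(3, 1, 4, 2), ])
  expect_equal(sort(sevick_clusters(fr, 3.5)$sizes),
               sort(sevick_clusters(fr_perm, 3.5)$sizes))
})

test_that("harvest collects each wanted size across frames", {
  ff <- water_models("SPC")$SPC
  frames <- lapply(1:4, function(s) {
    make_cluster_configuration(ff, ensemble_spec(5, seed = s))
  })
  h <- harvest_by_size(frames, r_cut = 3.5, wanted_sizes = c(5, 7))
  # generator links all 5 molecules within the connectivity range
  expect_gte(h$counts[["5"]], 1)
  expect_equal(h$counts[["7"]], 0L)
  expect_equal(nrow(h$occurrences[["7"]]), 0)
  # empty input and oversized requests are silent no-ops
  expect_equal(harvest_by_size(list(), 3.5, 3)$counts[["3"]], 0L)
  # stride skips frames
  h2 <- harvest_by_size(frames, 3.5, 5, stride = 2L)
  expect_true(all(h2$occurrences[["5"]]$frame %in% c(1, 3)))
})

test_that("XYZ round-trips frames and cluster CSVs are written", {
  ff <- water_models("SPC")$SPC
  frames <- lapply(1:2, function(s) {
    make_cluster_configuration(ff, ensemble_spec(3, seed = s))
  })
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, path)
  back <- read_xyz(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$coords, frames[[1]]$coords, tolerance = 1e-9)
  expect_equal(back[[2]]$elements, frames[[2]]$elements)
  csv <- withr::local_tempfile(fileext = ".csv")
  asg <- write_cluster_assignments(frames, 3.5, csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(asg), 2 * 3)
})
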