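test_that("generation is a pure function of the seed", {
  cfg <- synth_config(n_families = 3L, proteins_per_family = 4L,
                      length_range = c(30L, 80L), seed = 17L)
  r1 <- generate_proteins(cfg)
  r2 <- generate_proteins(cfg)
  expect_identical(r1, r2)
  r3 <- generate_proteins(synth_config(n_families = 3L,
                                       proteins_per_family = 4L,
                                       length_range = c(30L, 80L),
                                       seed = 18L))
  expect_false(identical(r1, r3))
})

test_that("a degenerate generator yields identical family members", {
  cfg <- synth_config(n_families = 2L, proteins_per_family = 3L,
                      length_range = c(30L, 60L), mutation_rate = 0,
                      coordinate_noise = 0, seed = 5L)
  recs <- generate_proteins(cfg)
  fam <- split(recs, vapply(recs, `[[`, "", "family"))
  for (members in fam) {
    for (m in members[-1]) {
      expect_identical(m$sequence, members[[1]]$sequence)
      expect_identical(m$coords, members[[1]]$coords)
    }
  }
  # between-family contact maps differ while within-family difference is 0
  cm <- function(r) featurize(distance_matrix(r$coords), 22,
                              max_len = 30L)$values
  expect_equal(sum((cm(fam[[1]][[1]]) - cm(fam[[1]][[2]]))^2), 0)
  expect_gt(sum((cm(fam[[1]][[1]]) - cm(fam[[2]][[1]]))^2), 0.1)
})

test_that("backbones have ~3.8 A consecutive C-alpha spacing before jitter", {
  cfg <- synth_config(n_families = 4L, proteins_per_family = 1L,
                      length_range = c(40L, 200L), mutation_rate = 0,
                      coordinate_noise = 0, seed = 23L)
  for (r in generate_proteins(cfg)) {
    gaps <- sqrt(rowSums(diff(r$coords)^2))
    expect_true(all(gaps > 3.5 & gaps < 4.1))
  }
  # with jitter, spacing stays within ~3 sigma of ideal
  noise <- 0.3
  recs <- generate_proteins(synth_config(n_families = 2L,
                                         proteins_per_family = 5L,
                                         length_range = c(40L, 80L),
                                         coordinate_noise = noise, seed = 24L))
  gaps <- unlist(lapply(recs, function(r) sqrt(rowSums(diff(r$coords)^2))))
  expect_true(mean(abs(gaps - 3.8) < 3 * sqrt(2) * noise + 0.05) > 0.99)
})

test_that("default family lengths span the truncation limit", {
  recs <- generate_proteins(synth_config(seed = 3L))
  lens <- vapply(recs, function(r) nchar(r$sequence), 1L)
  expect_true(all(lens >= 30L & lens <= 600L))
  expect_gt(sum(lens > 512L), 0)
  expect_equal(length(recs), 200L)
  expect_error(synth_config(length_range = c(5L, 20L), motif_length = 7L),
               "motif_length")
})

test_that("sequence 3-mers and contact patches both predict the family", {
  recs <- generate_proteins(synth_config(n_families = 4L,
                                         proteins_per_family = 10L,
                                         length_range = c(40L, 120L),
                                         seed = 31L))
  fams <- factor(vapply(recs, `[[`, "", "family"))
  # 3-mer composition features
  kmerize <- function(s) {
    n <- nchar(s)
    ks <- substring(s, 1:(n - 2), 3:n)
    table(factor(ks, levels = unique(unlist(
      lapply(recs, function(r) {
        m <- nchar(r$sequence)
        substring(r$sequence, 1:(m - 2), 3:m)
      })))))
  }
  K <- t(vapply(recs, function(r) as.numeric(kmerize(r$sequence)),
                numeric(length(kmerize(recs[[1]]$sequence)))))
  K <- K / pmax(rowSums(K), 1)
  # contact-map patch means on a fixed grid
  Pm <- t(vapply(recs, function(r) {
    si <- resize_for_encoder(featurize(distance_matrix(r$coords), 22),
                             side = 32, patch_size = 8)
    as.numeric(patchmeans <- vapply(seq_len(16), function(k) {
      pr <- (k - 1) %% 4; pc <- (k - 1) %/% 4
      mean(si$values[1, pr * 8 + 1:8, pc * 8 + 1:8])
    }, numeric(1)))
  }, numeric(16)))
  nearest_centroid_acc <- function(X) {
    train <- unlist(lapply(split(seq_along(fams), fams), head, 6))
    test <- setdiff(seq_along(fams), train)
    cents <- t(vapply(levels(fams), function(f)
      colMeans(X[intersect(train, which(fams == f)), , drop = FALSE]),
      numeric(ncol(X))))
    pred <- apply(test_d <- as.matrix(stats::dist(rbind(cents, X[test, ])))[
      -(1:nlevels(fams)), 1:nlevels(fams)], 1, which.min)
    mean(levels(fams)[pred] == fams[test])
  }
  expect_gt(nearest_centroid_acc(K), 0.5)       # chance = 0.25
  expect_gt(nearest_centroid_acc(Pm), 0.5)
})

test_that("a written corpus round-trips through the readers", {
  recs <- generate_proteins(synth_config(n_families = 2L,
                                         proteins_per_family = 3L,
                                         length_range = c(30L, 50L),
                                         seed = 41L))
  dir <- file.path(tempdir(), "corpus-rt")
  write_corpus(recs, dir)
  back <- read_corpus(dir)
  expect_equal(length(back), length(recs))
  ids <- vapply(recs, `[[`, "", "id")
  expect_false(any(duplicated(ids)))
  labs <- read.delim(file.path(dir, "labels.tsv"))
  expect_equal(nrow(labs), length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$id, recs[[i]]$id)
    expect_identical(back[[i]]$sequence, recs[[i]]$sequence)
    expect_identical(back[[i]]$family, recs[[i]]$family)
    expect_equal(back[[i]]$coords, recs[[i]]$coords, tolerance = 1e-5)
  }
})
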