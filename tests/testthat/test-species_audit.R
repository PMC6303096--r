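test_that("intraspecific stats: arithmetic, singletons, library mean", {
  labs <- c("a1", "a2", "a3", "b1")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  # species A pairwise distances 1.0%, 2.0%, 1.5% (substitutions/site inside)
  d["a1", "a2"] <- d["a2", "a1"] <- 0.010
  d["a1", "a3"] <- d["a3", "a1"] <- 0.020
  d["a2", "a3"] <- d["a3", "a2"] <- 0.015
  d[labs[1:3], "b1"] <- d["b1", labs[1:3]] <- 0.08
  lib <- make_lib(c("S a", "S a", "S a", "S b"),
                  rep(strrep("ACGT", 30), 4), ids = labs)
  st <- intraspecific_stats(fake_dm(d), lib)
  a_row <- st[st$species == "S a", ]
  expect_equal(a_row$max_intra, 2.0)
  expect_equal(a_row$mean_intra, 1.5)
  b_row <- st[st$species == "S b", ]
  expect_true(is.na(b_row$max_intra))          # singleton undefined
  expect_equal(attr(st, "mean_of_max"), 2.0)   # singleton excluded from the mean
})

test_that("intraspecific and nearest-neighbor stats match brute-force oracles", {
  sim <- simulate_library(sim_config(n_species = 8, specimens_per_species = c(3, 3, 2, 1, 4, 2, 3, 2),
                                     seq_length = 300, seed = 21))
  lib <- sim$library
  dm <- k2p_matrix(lib, min_overlap = 50)
  st <- intraspecific_stats(dm, lib)
  nn <- nearest_neighbor(dm, lib)
  sp <- lib$records$species
  ids <- lib$records$specimen_id
  for (s in unique(sp)) {
    mine <- ids[sp == s]; other <- ids[sp != s]
    # conspecific oracle
    if (length(mine) >= 2) {
      vals <- c()
      for (i in seq_along(mine)) for (j in seq_along(mine)) {
        if (i < j) vals <- c(vals, dm$distance[mine[i], mine[j]])
      }
      expect_equal(st$max_intra[st$species == s], 100 * max(vals), tolerance = 1e-12)
      expect_equal(st$mean_intra[st$species == s], 100 * mean(vals), tolerance = 1e-12)
    } else {
      expect_true(is.na(st$max_intra[st$species == s]))
    }
    # heterospecific oracle
    best <- Inf; best_sp <- NULL
    for (i in mine) for (j in other) {
      if (dm$distance[i, j] < best) { best <- dm$distance[i, j]; best_sp <- sp[ids == j] }
    }
    k <- which(nn$species == s)
    expect_equal(nn$nn_distance[k], 100 * best, tolerance = 1e-12)
    expect_true(best_sp %in% strsplit(nn$nn_ties[k], ",")[[1]])
  }
})

test_that("zero heterospecific distance means shared barcodes, symmetrically", {
  seqs <- c(strrep("ACGT", 40), strrep("ACGT", 40),  # identical across species
            strrep("ACGA", 40))
  lib <- make_lib(c("S a", "S b", "S c"), seqs)
  nn <- nearest_neighbor(k2p_matrix(lib, min_overlap = 50), lib)
  expect_equal(nn$nn_distance[nn$species == "S a"], 0)
  expect_equal(nn$shares_barcode_with[[which(nn$species == "S a")]], "S b")
  expect_equal(nn$shares_barcode_with[[which(nn$species == "S b")]], "S a")
  expect_length(nn$shares_barcode_with[[which(nn$species == "S c")]], 0)
})

mono_lib <- function(tips, species) {
  make_lib(species, rep(strrep("ACGT", 30), length(tips)), ids = tips)
}

test_that("monophyly classification follows the tree examples", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  lib1 <- mono_lib(c("a1", "a2", "b1", "b2"), c("S a", "S a", "S b", "S b"))
  m1 <- classify_monophyly(t1, lib1)
  expect_equal(as.character(m1$monophyly), c("monophyletic", "monophyletic"))

  t2 <- ape::read.tree(text = "((((b1:1,b2:1):1,a1:1):1,a2:1):1,a3:1);")
  lib2 <- mono_lib(c("b1", "b2", "a1", "a2", "a3"),
                   c("S b", "S b", "S a", "S a", "S a"))
  m2 <- classify_monophyly(t2, lib2)
  expect_equal(as.character(m2$monophyly[m2$species == "S a"]), "paraphyletic")
  expect_equal(as.character(m2$monophyly[m2$species == "S b"]), "monophyletic")
  expect_equal(m2$entangled_with[[which(m2$species == "S a")]], "S b")

  t3 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  lib3 <- mono_lib(c("a1", "b1", "a2", "b2"), c("S a", "S b", "S a", "S b"))
  m3 <- classify_monophyly(t3, lib3)
  expect_equal(as.character(m3$monophyly), c("polyphyletic", "polyphyletic"))

  lib4 <- mono_lib(c("a1", "a2", "b1", "c1"), c("S a", "S a", "S b", "S c"))
  t4 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,c1:1):1);")
  m4 <- classify_monophyly(t4, lib4)
  expect_equal(as.character(m4$monophyly),
               c("monophyletic", "singleton", "singleton"))

  expect_error(classify_monophyly(t4, lib3), class = "input_error")
})

test_that("diagnosability criteria follow the cluster and haplotype rules", {
  # paraphyletic donor/recipient pair with species-specific haplotypes:
  # cluster false, haplotype true
  t2 <- ape::read.tree(text = "((((b1:1,b2:1):1,a1:1):1,a2:1):1,a3:1);")
  lib2 <- mono_lib(c("b1", "b2", "a1", "a2", "a3"),
                   c("S b", "S b", "S a", "S a", "S a"))
  # distances: make all sequences distinct so no sharing
  lib2$records$sequence <- vapply(1:5, function(i) {
    s <- strrep("ACGT", 30); substr(s, i, i) <- "T"; s
  }, character(1))
  audit <- species_audit(lib2, tree = t2, min_overlap = 50)
  a <- audit$assessments
  expect_false(a$cluster_diagnostic[a$species == "S a"])
  expect_true(a$haplotype_diagnostic[a$species == "S a"])
  expect_true(a$cluster_diagnostic[a$species == "S b"])

  # singleton identical to another species' haplotype: both criteria false
  seqs <- c(strrep("ACGT", 40), strrep("ACGT", 40), strrep("ACGA", 40))
  lib <- make_lib(c("S a", "S a2", "S c"), seqs)
  aud <- species_audit(lib, min_overlap = 50)
  row <- aud$assessments[aud$assessments$species == "S a", ]
  expect_equal(as.character(row$monophyly), "singleton")
  expect_false(row$cluster_diagnostic)
  expect_false(row$haplotype_diagnostic)
  # monophyletic species with positive nearest neighbor: both true
  rowc <- aud$assessments[aud$assessments$species == "S c", ]
  expect_true(rowc$cluster_diagnostic && rowc$haplotype_diagnostic)
})

test_that("cryptic flags use strict thresholds and skip singletons", {
  a <- data.frame(species = c("x", "y", "z"), max_intra = c(5.63, 2.0, NA))
  fl <- cryptic_flags(a, thresholds = c(2, 3))
  expect_equal(fl$over_2pct, c(TRUE, FALSE, FALSE))  # 2.0 exactly: not over 2
  expect_equal(fl$over_3pct, c(TRUE, FALSE, FALSE))
})

test_that("identify_query matches, ties and rejects correctly", {
  seqs <- c(strrep("ACGT", 40), strrep("ACGA", 40), strrep("ACGA", 40))
  lib <- make_lib(c("S x", "S y", "S z"), seqs)
  hit <- identify_query(strrep("ACGT", 40), lib, threshold = 2, min_overlap = 50)
  expect_equal(hit$status, "match")
  expect_equal(hit$species, "S x")
  expect_equal(hit$distance, 0)

  tie <- identify_query(strrep("ACGA", 40), lib, threshold = 2, min_overlap = 50)
  expect_equal(tie$status, "ambiguous")
  expect_equal(tie$species, c("S y", "S z"))

  far <- paste(rep(c("G", "T", "C", "A"), 40), collapse = "")
  no <- identify_query(far, lib, threshold = 2, min_overlap = 50)
  expect_equal(no$status, "no_match")
})

test_that("audit invariants hold across simulated libraries", {
  for (seed in c(2, 4, 6)) {
    sim <- simulate_library(sim_config(
      n_species = 8, specimens_per_species = c(4, 4, 3, 1, 1, 3, 2, 2),
      seq_length = 400, seed = seed,
      introgression_events = data.frame(donor = 1, recipient = 2, n_specimens = 1)))
    aud <- species_audit(sim$library, min_overlap = 50)
    a <- aud$assessments
    # partition property
    expect_equal(sum(unlist(aud$summary$monophyly_counts)), nrow(a))
    # cluster-diagnostic species are a subset of haplotype-diagnostic species
    expect_true(all(!a$cluster_diagnostic | a$haplotype_diagnostic))
    # sharing is symmetric and equivalent to nn_distance == 0
    for (k in seq_len(nrow(a))) {
      sh <- a$shares_barcode_with[[k]]
      expect_identical(length(sh) > 0, a$nn_distance[k] == 0)
      for (s in sh) {
        expect_true(a$species[k] %in% a$shares_barcode_with[[which(a$species == s)]])
      }
    }
    # the introgressed pair is flagged on both sides
    donor <- sim$species_truth$species[1]; recip <- sim$species_truth$species[2]
    expect_true(recip %in% a$shares_barcode_with[[which(a$species == donor)]])
    expect_false(a$haplotype_diagnostic[a$species == donor])
    expect_false(a$haplotype_diagnostic[a$species == recip])
  }
})
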