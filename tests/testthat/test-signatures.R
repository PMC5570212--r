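test_that("cutoff schedules enumerate the expected thresholds", {
  expect_equal(cutoff_schedule(0, 10, 2)$cutoffs, c(0, 2, 4, 6, 8, 10))
  expect_equal(length(cutoff_schedule(1, 8, 3)$cutoffs), 3)
  expect_error(cutoff_schedule(5, 4, 1), "invalid")
  expect_error(cutoff_schedule(0, 10, 0), "invalid")
})

test_that("a single atom pair lands in the right cells", {
  atoms <- data.frame(x = c(0, 3), y = c(0, 0), z = c(0, 0))
  labels <- list("hydrophobic", "positive")
  pc <- cutoff_scan(atoms, labels, cutoff_schedule(2, 4, 2))
  expect_equal(unname(pc["hydrophobic|positive", ]), c(0, 1))
  expect_equal(sum(pc), 1)
})

test_that("a single atom yields an all-zero scan and empty input errors", {
  atoms <- data.frame(x = 0, y = 0, z = 0)
  pc <- cutoff_scan(atoms, list("hydrophobic"), cutoff_schedule())
  expect_true(all(pc == 0))
  expect_error(cutoff_scan(atoms[0, ], list(), cutoff_schedule()), "empty")
})

test_that("multi-class atoms contribute once per distinct class pair", {
  atoms <- data.frame(x = c(0, 1), y = c(0, 0), z = c(0, 0))
  labels <- list(c("positive", "hb_donor"), c("positive", "hb_donor"))
  pc <- cutoff_scan(atoms, labels, cutoff_schedule(0, 2, 2))
  expect_equal(unname(pc["positive|positive", "2"]), 1)
  expect_equal(unname(pc["positive|hb_donor", "2"]), 1)
  expect_equal(unname(pc["hb_donor|hb_donor", "2"]), 1)
  expect_equal(sum(pc[, "2"]), 3)
})

test_that("cutoff_scan equals the brute-force oracle on random clouds", {
  sched <- cutoff_schedule(0, 10, 2)
  for (seed in 1:10) {
    cl <- random_atom_cloud(30, seed)
    fast <- cutoff_scan(cl$atoms, cl$labels, sched)
    slow <- bf_cutoff_scan(cl$atoms, cl$labels, sched)
    expect_equal(fast, slow, info = paste("seed", seed))
  }
})

test_that("signatures are cumulative and monotone under schedule extension", {
  cl <- random_atom_cloud(40, 99)
  pc <- cutoff_scan(cl$atoms, cl$labels, cutoff_schedule(0, 10, 2))
  expect_true(all(apply(pc, 1, function(r) all(diff(r) >= 0))))
  pc2 <- cutoff_scan(cl$atoms, cl$labels, cutoff_schedule(0, 20, 2))
  expect_true(all(pc2[, "10"] <= pc2[, "20"]))
  expect_equal(pc2[, colnames(pc)], pc)
})

test_that("signatures are invariant to atom order and rigid motion", {
  sched <- cutoff_schedule(0, 10, 2)
  cl <- random_atom_cloud(25, 5)
  base <- cutoff_scan(cl$atoms, cl$labels, sched)
  perm <- withr::with_seed(1, sample(nrow(cl$atoms)))
  expect_equal(cutoff_scan(cl$atoms[perm, ], cl$labels[perm], sched), base)
  moved <- rigid_transform(cl$atoms)
  expect_equal(cutoff_scan(moved, cl$labels, sched), base, tolerance = 1e-9)
})

test_that("build_signature is deterministic and manifest-shaped", {
  cx <- helix_complex(seed = 7)
  cfg <- na_config()
  v1 <- build_signature(cx, "R12C", cfg, chain = "A")
  v2 <- build_signature(cx, "R12C", cfg, chain = "A")
  expect_identical(v1, v2)
  expect_equal(names(v1), signature_manifest(cfg))
  expect_equal(unname(v1[c("na.RNA", "na.ssDNA", "na.dsDNA")]), c(0, 0, 1))
})

test_that("a tiny radius restricts the scan to intra-residue pairs", {
  cx <- helix_complex(seed = 7)
  cfg <- na_config(radius = 0.1)
  v <- build_signature(cx, "R12C", cfg, chain = "A")
  res <- locate_residue(cx, mutation_spec("R12C", "A"))
  own <- cx$atoms[res$atom_idx, ]
  labels <- nabind:::atom_class_sets(own, scheme = "NUC_GROUP")
  pc <- bf_cutoff_scan(own, labels, cfg$schedule)
  expect_equal(unname(v[seq_len(length(pc))]),
               as.vector(t(pc)))
  # no nucleic-acid atom in range: all NA-class pair cells are zero
  na_cells <- grepl("na_", names(v)[seq_len(length(pc))])
  expect_true(all(v[seq_len(length(pc))][na_cells] == 0))
})

test_that("an interface arginine registers positive-phosphate contacts", {
  cx <- helix_complex(seed = 7, contact_distance = 3.0)
  v <- build_signature(cx, "R12C", na_config(), chain = "A")
  expect_gt(v["pc.positive|na_phosphate.4"], 0)
  expect_equal(unname(v["dist_na"]), 3.0, tolerance = 1e-6)
})

test_that("the base-scheme config produces its own manifest and signature", {
  cx <- helix_complex(seed = 7)
  cfg <- na_config(scheme = "NUC_BASE")
  v <- build_signature(cx, "R12C", cfg, chain = "A")
  expect_equal(names(v), signature_manifest(cfg))
  expect_true(any(grepl("na_purine|na_pyrimidine", names(v))))
  expect_false(any(grepl("na_phosphate", names(v))))
})

test_that("signature matrices round-trip through TSV with their manifest", {
  d <- generate_planted_dataset(n_records = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(d$X, path)
  back <- read_signatures(path)
  expect_equal(back$manifest, colnames(d$X))
  expect_equal(unname(back$X), unname(d$X), tolerance = 1e-8)
  # corrupt the sidecar -> refused
  writeLines(rev(back$manifest), paste0(path, ".manifest"))
  expect_error(read_signatures(path), "manifest")
})
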