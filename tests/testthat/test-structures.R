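test_that("a minimal complex parses with correct chain kinds", {
  cx <- parse_complex(toy_pdb(), na_type = "dsDNA")
  expect_s3_class(cx, "na_complex")
  expect_equal(cx$chains, c(A = "protein", B = "nucleic_acid"))
  expect_equal(nrow(unique(cx$atoms[, c("chain", "resno")])), 2)
  expect_equal(cx$na_type, "dsDNA")
})

test_that("structures without both molecule types are rejected", {
  expect_error(parse_complex(toy_pdb(drop_na = TRUE), na_type = "dsDNA"),
               "no nucleic-acid chain")
  na_only <- paste(strsplit(toy_pdb(), "\n")[[1]][6:9], collapse = "\n")
  expect_error(parse_complex(na_only, na_type = "dsDNA"), "no protein chain")
})

test_that("hydrogens and waters are dropped, HETATM kept as 'other'", {
  extra <- c(
    "ATOM      9  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM   10  O   HOH A  99      12.000  12.000  12.000  1.00  0.00           O",
    "HETATM   11 MG    MG A  98      13.000  13.000  13.000  1.00  0.00          MG")
  txt <- paste(c(strsplit(toy_pdb(), "\n")[[1]][1:8], extra, "END"),
               collapse = "\n")
  expect_message(cx <- parse_complex(txt, na_type = "dsDNA"),
                 "non-standard residue")
  expect_false(any(cx$atoms$element == "H"))
  expect_false(any(cx$atoms$resid == "HOH"))
  expect_true(any(cx$atoms$kind == "other"))
  # 'other' atoms never enter the environment
  env <- extract_environment(cx, mutation_spec("A1G", "A"), radius = 1e6)
  expect_false(any(env$kind == "other"))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  base <- strsplit(toy_pdb(), "\n")[[1]]
  alt <- c(
    "ATOM      5  CB AALA A   1       1.988  -0.773  -1.199  0.60  0.00           C",
    "ATOM      6  CB BALA A   1       2.300  -0.500  -1.000  0.40  0.00           C")
  # splice altloc CB pair in place of the single CB
  txt <- paste(c(base[1:4], alt, base[6:9]), collapse = "\n")
  cx <- parse_complex(txt, na_type = "dsDNA")
  cb <- cx$atoms[cx$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$alt, "A")
  expect_equal(cb$x, 1.988, tolerance = 1e-6)
  # tie in occupancy -> alphabetically first altloc id
  alt_tie <- sub("0.60", "0.40", alt[1])
  txt2 <- paste(c(base[1:4], alt_tie, alt[2], base[6:9]), collapse = "\n")
  cx2 <- parse_complex(txt2, na_type = "dsDNA")
  expect_equal(cx2$atoms$alt[cx2$atoms$elety == "CB"], "A")
})

test_that("altloc resolution on a generated fixture matches a brute-force filter", {
  # duplicate one residue's side chain as a lower-occupancy B conformer
  cx <- helix_complex(seed = 50)
  lines <- write_complex(cx)
  res3 <- cx$atoms$resno == 3 & cx$atoms$chain == "A" &
    !cx$atoms$elety %in% c("N", "CA", "C", "O")
  n_side <- sum(res3)
  skip_if(n_side == 0)
  sel <- which(res3)
  a_lines <- b_lines <- write_complex(cx)[sel]
  substr(a_lines, 17, 17) <- "A"; substr(a_lines, 57, 60) <- "0.60"
  substr(b_lines, 17, 17) <- "B"; substr(b_lines, 57, 60) <- "0.40"
  all_lines <- c(write_complex(cx)[-c(sel, length(lines))], a_lines, b_lines, "END")
  cx2 <- parse_complex(paste(all_lines, collapse = "\n"), na_type = "dsDNA")
  got <- cx2$atoms[cx2$atoms$resno == 3 & cx2$atoms$chain == "A", ]
  # brute-force expectation: all non-alt atoms + only the A-conformer atoms
  expect_equal(sum(got$alt == "B"), 0)
  expect_equal(sum(got$alt == "A"), n_side)
  expect_equal(nrow(got), sum(cx$atoms$resno == 3 & cx$atoms$chain == "A"))
})

test_that("malformed ATOM records are reported with their line number", {
  bad <- strsplit(toy_pdb(), "\n")[[1]]
  bad[3] <- "ATOM      3  C   ALA A   1       2.009   1.4xx   0.000  1.00"
  expect_error(parse_complex(paste(bad, collapse = "\n"), na_type = "dsDNA"),
               "line 3")
})

test_that("multi-model files use MODEL 1 with a warning", {
  base <- strsplit(toy_pdb(), "\n")[[1]]
  txt <- paste(c("MODEL     1", base[1:8], "ENDMDL",
                 "MODEL     2", base[1:8], "ENDMDL", "END"), collapse = "\n")
  expect_warning(cx <- parse_complex(txt, na_type = "dsDNA"), "MODEL 1")
  expect_equal(nrow(cx$atoms), 8)
})

test_that("locate_residue finds residues and guards the wild type", {
  cx <- helix_complex(seed = 7)  # interface ARG at A:12
  res <- locate_residue(cx, mutation_spec("R12C", "A"))
  expect_equal(res$resid, "ARG")
  expect_error(locate_residue(cx, mutation_spec("K12C", "A")),
               "ARG")
  expect_error(locate_residue(cx, mutation_spec("R999C", "A")), "not found")
})

test_that("insertion codes must match exactly", {
  base <- strsplit(toy_pdb(), "\n")[[1]]
  ins <- base[1:5]
  substr(ins, 27, 27) <- "A"  # icode column
  txt <- paste(c(ins, base[6:9]), collapse = "\n")
  cx <- parse_complex(txt, na_type = "dsDNA")
  expect_error(locate_residue(cx, mutation_spec("A1G", "A")), "not found")
  res <- locate_residue(cx, mutation_spec("A1AG", "A"))
  expect_equal(res$insert, "A")
})

test_that("mutation strings parse and serialize", {
  m <- mutation_spec("R273C", "A")
  expect_equal(m$wt, "R"); expect_equal(m$resno, 273L); expect_equal(m$mut, "C")
  expect_equal(format_mutation(m), "R273C")
  expect_equal(format_mutation(mutation_spec("T100AG", "B")), "T100AG")
  expect_error(mutation_spec("R273R", "A"), "identical")
  expect_error(mutation_spec("X273C", "A"), "standard")
  expect_error(mutation_spec("273C", "A"), "parse")
})

test_that("environment extraction matches a brute-force all-pairs oracle", {
  cx <- helix_complex(seed = 13, n_protein_residues = 14, n_na_residues = 8)
  m <- mutation_spec("R14A", "A")
  res <- locate_residue(cx, m)
  for (radius in c(4, 8, 12)) {
    env <- extract_environment(cx, m, radius = radius)
    # brute force over all atom pairs
    at <- cx$atoms[cx$atoms$kind != "other", ]
    ref <- as.matrix(cx$atoms[res$atom_idx, c("x", "y", "z")])
    keep <- vapply(seq_len(nrow(at)), function(i) {
      p <- as.numeric(at[i, c("x", "y", "z")])
      any(sqrt(colSums((t(ref) - p)^2)) <= radius)
    }, logical(1))
    expect_setequal(paste(env$chain, env$resno, env$elety),
                    paste(at$chain, at$resno, at$elety)[keep])
  }
})

test_that("environment limits: infinite radius and self-only radius", {
  cx <- parse_complex(toy_pdb(), na_type = "dsDNA")
  all_env <- extract_environment(cx, mutation_spec("A1G", "A"), radius = 1e9)
  expect_equal(nrow(all_env), nrow(cx$atoms))
  self_env <- extract_environment(cx, mutation_spec("A1G", "A"), radius = 0.1)
  expect_setequal(self_env$elety, c("N", "CA", "C", "O", "CB"))
  expect_error(extract_environment(cx, mutation_spec("A1G", "A"), radius = 0),
               "radius")
})

test_that("environment membership is monotone in radius", {
  cx <- helix_complex(seed = 23)
  m <- mutation_spec("R12A", "A")
  prev <- NULL
  for (r in c(2, 4, 6, 8, 10, 15)) {
    env <- extract_environment(cx, m, radius = r)
    ids <- paste(env$chain, env$resno, env$elety)
    if (!is.null(prev)) expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("parse -> serialize -> parse preserves atoms and coordinates", {
  cx <- helix_complex(seed = 31)
  cx2 <- parse_complex(paste(write_complex(cx), collapse = "\n"),
                       na_type = cx$na_type)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  for (col in c("x", "y", "z"))
    expect_equal(cx2$atoms[[col]], cx$atoms[[col]], tolerance = 1e-3)
  expect_equal(cx2$atoms$elety, cx$atoms$elety)
})
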