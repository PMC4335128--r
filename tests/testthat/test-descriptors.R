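test_that("structure standardization keeps the largest organic fragment", {
  out <- standardize_structures(c(a = "CCO", b = "[Na+].[Cl-]",
                                  c = "CC(=O)O.[Na+]", d = "xx(((bad"))
  expect_equal(out$standardized_smiles[out$compound_id == "a"], "CCO")
  expect_false(out$kept[out$compound_id == "b"])
  expect_equal(out$reason[out$compound_id == "b"], "inorganic")
  expect_equal(out$standardized_smiles[out$compound_id == "c"], "CC(=O)O")
  expect_equal(out$reason[out$compound_id == "d"], "unparseable")
})

test_that("vocabulary enumerates circular environments with collapsed symmetry", {
  v_benz <- build_substructure_vocabulary("c1ccccc1")
  expect_s3_class(v_benz, "substructure_vocab")
  expect_equal(nrow(v_benz), 3)            # one id per radius
  expect_equal(sort(v_benz$radius), 0:2)
  counts <- unhashed_morgan_counts("c1ccccc1", v_benz)
  expect_equal(unname(counts), c(6L, 6L, 6L))

  # ethane: the radius-2 ball adds no bonds over radius 1
  v_eth <- build_substructure_vocabulary("CC")
  expect_equal(nrow(v_eth), 2)
  expect_equal(sort(v_eth$radius), 0:1)

  expect_error(build_substructure_vocabulary(character(0)), "empty")
  # vocabulary order is deterministic (sorted by id)
  expect_equal(v_benz$substructure_id, sort(v_benz$substructure_id))
})

test_that("keyed counts are closed-world and cover every heavy atom at radius 0", {
  v_benz <- build_substructure_vocabulary("c1ccccc1")
  # molecule sharing no environment with the vocabulary -> zero vector
  expect_equal(sum(unhashed_morgan_counts("OCCO", v_benz)), 0L)

  st <- small_study()
  smiles <- st$compounds$smiles[1:25]
  vocab <- build_substructure_vocabulary(smiles)
  m <- morgan_count_matrix(setNames(smiles, paste0("M", 1:25)), vocab)
  r0_cols <- vocab$radius == 0
  heavy <- vapply(smiles, function(s) pcmens:::smiles_to_graph(s)$n_atoms,
                  integer(1))
  expect_equal(unname(rowSums(m[, r0_cols, drop = FALSE])), unname(heavy))
  expect_error(unhashed_morgan_counts("bad(((", vocab), "unparseable")
})

test_that("z-scale descriptors concatenate the five scales over selected columns", {
  zs <- zscale_matrix()
  expect_equal(dim(zs), c(20L, 5L))
  expect_equal(rownames(zs)[1], "A")

  tg <- generate_targets(11, n_positions = 25, seed = 3)
  block <- zscale_descriptors(tg$sequences, tg$selected_columns)
  expect_equal(dim(block), c(11L, 125L))

  # identical sequences give identical rows; lookup of a single column
  b2 <- zscale_descriptors(c(s1 = "AC", s2 = "AC"), 1)
  expect_equal(b2["s1", ], b2["s2", ])
  expect_equal(unname(b2["s1", ]), unname(zs["A", ]))

  # gap -> five zeros, distinct from every residue row
  bg <- zscale_descriptors(c(s1 = "A-C"), 2)
  expect_equal(unname(bg[1, ]), rep(0, 5))

  expect_error(zscale_descriptors(c(s1 = "AXC"), 1:3), "non-standard residue")
  expect_error(zscale_descriptors(c(s1 = "AC", s2 = "ACD")), "differ in length")
  expect_error(zscale_descriptors(c(s1 = "AC"), 5), "bounds")

  # permutation equivariance
  seqs <- tg$sequences
  perm <- rev(seq_along(seqs))
  expect_equal(zscale_descriptors(seqs[perm]),
               zscale_descriptors(seqs)[perm, ])
})

test_that("z-scale descriptors read aligned FASTA", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ACDEF", ">t2", "ACDEW"), f)
  b <- zscale_descriptors(f, c(1, 5))
  expect_equal(rownames(b), c("t1", "t2"))
  expect_equal(unname(b["t2", 6:10]), unname(zscale_matrix()["W", ]))
})

test_that("near-zero-variance filter applies the 30/1 frequency-ratio rule", {
  x <- cbind(
    const = rep(1, 62),
    ratio31 = c(rep(0, 61), 1),            # top 61 / second 1 > 30 -> removed
    ratio30 = c(rep(0, 60), 1, 1),         # 60 / 2 = 30, not > 30 -> kept
    ok = rep_len(c(0, 1, 2), 62)
  )
  out <- remove_near_zero_variance(x)
  expect_equal(unname(out$kept), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(colnames(out$x), c("ratio30", "ok"))
  expect_error(remove_near_zero_variance(x[, "const", drop = FALSE]),
               "all columns removed")
})

test_that("centering and scaling use training statistics with the n-1 SD", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  cs <- center_scale(x)
  expect_equal(unname(cs$x[, "a"]), c(-1, 0, 1))
  # idempotence on refit
  cs2 <- center_scale(cs$x)
  expect_equal(cs2$x, cs$x, tolerance = 1e-12)
  # held-out row equal to the training mean maps to zero
  prep <- preprocess_fit(rbind(x, colMeans(x)), fit_rows = 1:3,
                         ratio_cutoff = Inf)
  expect_equal(unname(prep$x[4, ]), c(0, 0), tolerance = 1e-12)
  expect_error(center_scale(cbind(z = rep(2, 4))), "zero training SD")
})

test_that("fitted preprocessing state survives serialization bit-identically", {
  st <- small_study()
  prep <- st$prep
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(prep, f)
  prep2 <- readRDS(f)
  rows <- st$design$x[1:10, , drop = FALSE]
  expect_identical(preprocess_apply(prep, rows), preprocess_apply(prep2, rows))
})

test_that("PCM design assembly concatenates compound and target blocks", {
  cb <- matrix(1:6, nrow = 3, dimnames = list(c("C1", "C2", "C3"), c("f1", "f2")))
  tb <- matrix(1:4, nrow = 2, dimnames = list(c("T1", "T2"), c("z1", "z2")))
  tab <- bioactivity_table(tibble::tibble(
    compound_id = c("C1", "C1", "C2", "C3"),
    target_id = c("T1", "T2", "T1", "T2"),
    pIC50 = c(5, 6, 7, 8)
  ))
  d <- assemble_pcm_matrix(cb, tb, tab)
  expect_equal(dim(d$x), c(4L, 4L))
  expect_equal(d$y, tab$pIC50)
  # same compound on two targets: identical compound columns, differing target
  expect_equal(d$x[1, d$compound_cols], d$x[2, d$compound_cols])
  expect_false(all(d$x[1, d$target_cols] == d$x[2, d$target_cols]))
  # ablations: one block only
  expect_equal(ncol(assemble_pcm_matrix(cb, NULL, tab)$x), 2L)
  expect_equal(ncol(assemble_pcm_matrix(NULL, tb, tab)$x), 2L)
  expect_error(assemble_pcm_matrix(cb, tb, tab[0, ]), "empty")
  expect_error(
    assemble_pcm_matrix(cb[1:2, ], tb, tab),
    "missing compound"
  )
})

test_that("vocabulary and preprocessing JSON round-trips are exact", {
  v <- build_substructure_vocabulary(c("c1ccccc1", "CCO"))
  f <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_equal(v2$substructure_id, v$substructure_id)
  expect_equal(v2$radius, v$radius)
  expect_equal(unhashed_morgan_counts("c1ccccc1", v2),
               unhashed_morgan_counts("c1ccccc1", v))

  st <- small_study()
  fp <- withr::local_tempfile(fileext = ".json")
  write_preprocess(st$prep, fp)
  prep2 <- read_preprocess(fp)
  rows <- st$design$x[1:8, , drop = FALSE]
  expect_equal(preprocess_apply(prep2, rows), preprocess_apply(st$prep, rows))
})
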