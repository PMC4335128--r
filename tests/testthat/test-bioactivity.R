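records_tbl <- function(...) {
  tibble::tribble(
    ~compound_id, ~smiles, ~target_id, ~value, ~relationship, ~unit, ~assay_confidence,
    ...
  )
}

test_that("delimited exports parse through a column map, skipping bad values", {
  f <- write_bioactivity_csv(c(
    "cid,smi,tid,val,rel,u,conf",
    "C1,CCO,T1,100,=,nM,9",
    "C2,CCN,T1,250,=,nM,8",
    "C3,CCC,T2,10,=,nM,9"
  ))
  map <- c(compound_id = "cid", smiles = "smi", target_id = "tid",
           value = "val", relationship = "rel", unit = "u",
           assay_confidence = "conf")
  out <- parse_bioactivity_table(f, map)
  expect_equal(nrow(out), 3)
  expect_type(out$value, "double")
  expect_equal(out$assay_confidence, c(9L, 8L, 9L))

  f_empty <- write_bioactivity_csv("cid,smi,tid,val,rel,u,conf")
  expect_equal(nrow(parse_bioactivity_table(f_empty, map)), 0)

  f_bad <- write_bioactivity_csv(c(
    "cid,smi,tid,val,rel,u,conf",
    "C1,CCO,T1,n/a,=,nM,9",
    "C2,CCN,T1,50,=,nM,9"
  ))
  expect_warning(out_bad <- parse_bioactivity_table(f_bad, map), "skipped")
  expect_equal(nrow(out_bad), 1)

  # tab-delimited autodetection
  f_tab <- write_bioactivity_csv(c(
    "cid\tsmi\ttid\tval\trel\tu\tconf",
    "C1\tCCO\tT1\t100\t=\tnM\t9"
  ))
  expect_equal(nrow(parse_bioactivity_table(f_tab, map)), 1)

  expect_error(parse_bioactivity_table(f, map[-1]), "column_map")
  expect_error(parse_bioactivity_table(f, c(map[-1], compound_id = "nope")),
               "not present")
})

test_that("quality filters keep exact nM records above the confidence cut", {
  recs <- records_tbl(
    "C1", "CCO", "T1", 100, "=",  "nM", 8L,
    "C2", "CCO", "T1", 100, ">",  "nM", 9L,
    "C3", "CCO", "T1", 100, "=",  "uM", 9L,
    "C4", "CCO", "T1", 100, "=",  "nM", 7L,
    "C5", "CCO", "T1", 100, " = ", "NM", 9L
  )
  out <- apply_quality_filters(recs)
  expect_equal(out$compound_id, c("C1", "C5"))  # whitespace + case tolerated
  rej <- attr(out, "rejections")
  expect_equal(rej$n_rejected[rej$rule == "relationship_not_equality"], 1)
  expect_equal(rej$n_rejected[rej$rule == "unit_not_nM"], 1)
  expect_equal(rej$n_rejected[rej$rule == "confidence_below_threshold"], 1)
  # idempotence
  expect_equal(apply_quality_filters(out)$compound_id, out$compound_id)
})

test_that("pIC50 conversion follows the molar convention", {
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(50), 7.30103, tolerance = 1e-6)
  expect_error(to_pic50(0), "positive")
  expect_error(to_pic50(-5), "positive")
  # strictly decreasing, decade-shift property
  x <- withr::with_seed(1, runif(50, 0.1, 1e5))
  expect_true(all(diff(to_pic50(sort(x))) < 0))
  expect_equal(to_pic50(10 * x), to_pic50(x) - 1)
})

test_that("deduplication averages replicates per compound-target pair", {
  recs <- records_tbl(
    "C1", "CCO", "T1", 1000, "=", "nM", 9L,   # pIC50 6
    "C1", "CCO", "T1", 100,  "=", "nM", 9L,   # pIC50 7
    "C2", "CCN", "T1", 10^(9 - 8.2), "=", "nM", 9L,
    "C1", "CCO", "T2", 10,   "=", "nM", 9L
  )
  tab <- deduplicate(recs)
  expect_s3_class(tab, "bioactivity_table")
  expect_equal(nrow(tab), 3)   # 4 records over 3 distinct pairs
  p11 <- tab[tab$compound_id == "C1" & tab$target_id == "T1", ]
  expect_equal(p11$pIC50, 6.5)
  expect_equal(p11$n_source_records, 2L)
  expect_equal(tab$pIC50[tab$compound_id == "C2"], 8.2)
  # output size equals distinct pairs for random inputs
  recs2 <- withr::with_seed(4, tibble::tibble(
    compound_id = paste0("C", sample(1:6, 20, TRUE)),
    smiles = "CCO",
    target_id = paste0("T", sample(1:3, 20, TRUE)),
    value = runif(20, 1, 1000),
    relationship = "=", unit = "nM", assay_confidence = 9L
  ))
  tab2 <- deduplicate(recs2)
  expect_equal(nrow(tab2),
               nrow(dplyr::distinct(recs2, compound_id, target_id)))
})

test_that("summaries report counts and completeness consistently", {
  tab <- bioactivity_table(tibble::tibble(
    compound_id = "C1", target_id = "T1", pIC50 = 7
  ))
  s <- summarize_bioactivity(tab)
  expect_equal(s$completeness_pct, 100)
  st <- small_study()
  s2 <- summarize_bioactivity(st$table)
  expect_equal(
    s2$completeness_pct,
    100 * s2$n_datapoints / (s2$n_compounds * s2$n_targets),
    tolerance = 1e-12
  )
  expect_error(summarize_bioactivity(tab[0, ]), "empty")
})

test_that("selectivity comparison pairs dual-annotated compounds", {
  tab <- bioactivity_table(tibble::tibble(
    compound_id = rep(paste0("C", 1:4), 2),
    target_id = rep(c("T1", "T2"), each = 4),
    pIC50 = c(5, 6, 7, 8, 8.2, 5.1, 7.5, 5.9)
  ))
  sel <- selectivity_comparison(tab, "T1", "T2")
  expect_equal(sel$n_shared, 4)
  expect_equal(sel$rmse, rmse(tab$pIC50[5:8], tab$pIC50[1:4]))
  expect_equal(sel$r2_zero, r2_zero(tab$pIC50[5:8], tab$pIC50[1:4])$r2_zero)
  expect_error(selectivity_comparison(tab, "T1", "T9"), "unknown target")
})
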