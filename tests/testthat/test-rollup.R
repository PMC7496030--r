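# minimal hand-built quant/component fixtures: rollup maths is pure tabular
fake_components <- function() {
  tibble::tibble(
    component_id = c("P|mod|mc0", "P|none|mc0", "Pmc|mod|mc1", "Pmc|none|mc1"),
    sequence = c("P", "P", "Pmc", "Pmc"), modification = c("mod", "none", "mod", "none"),
    site_label = "s", attribute = c("attr", NA, "attr", NA), mode = "pairwise",
    role = c("modified", "reference", "modified", "reference"),
    pair_key = "P", missed_cleavages = c(0L, 0L, 1L, 1L), specific = TRUE,
    mc_parent = c(NA, NA, "P|mod|mc0", "P|none|mc0"),
    include_in_rollup = TRUE, abundance_scale = 1, mono_mass = 1000,
    rt_resolved = FALSE, expected_rt_min = 20, charges = "2",
    isobaric_group = FALSE, rt_window_min = 1.5,
    chain_id = NA_character_, start = NA_integer_, end = NA_integer_
  )
}

fake_quant <- function(areas, found = rep(TRUE, length(areas)),
                       ids = fake_components()$component_id[seq_along(areas)]) {
  tibble::tibble(lab = 1, replicate = 1, component_id = ids,
                 apex_rt = 20, area = areas, found = found)
}

test_that("pairwise relative abundance is the modified share of the pair", {
  comp <- fake_components()[1:2, ]
  ra <- relative_abundance(fake_quant(c(12, 88)), comp)
  expect_equal(ra$value, 12.0)
  # scaling invariance
  ra2 <- relative_abundance(fake_quant(c(12, 88) * 7), comp)
  expect_equal(ra2$value, ra$value)
})

test_that("proportional missed-cleavage partners leave the value unchanged", {
  comp <- fake_components()
  base <- relative_abundance(fake_quant(c(12, 88), ids = comp$component_id[1:2]),
                             comp[1:2, ])
  with_mc <- relative_abundance(fake_quant(c(12, 88, 12 * 0.15, 88 * 0.15)), comp)
  expect_equal(with_mc$value, base$value)
})

test_that("zero denominators are flagged undefined, never reported as 0", {
  comp <- fake_components()[1:2, ]
  ra <- relative_abundance(fake_quant(c(0, 0), found = c(FALSE, FALSE)), comp)
  expect_false(ra$defined)
  expect_true(is.na(ra$value))
})

test_that("glycoform profiles normalise to 100 and keep isomer separation", {
  tr <- make_ground_truth("nist_table1", lab = "ireland")
  comp <- build_component_table(truth = tr)
  prof_comp <- comp[comp$role == "profile" & comp$missed_cleavages == 0 &
                      !comp$isobaric_group, ]
  q <- fake_quant(rep(100, nrow(prof_comp)), ids = prof_comp$component_id)
  gp <- glycan_profile(q, prof_comp)
  expect_equal(gp$value, rep(100 / nrow(prof_comp), nrow(prof_comp)))
  expect_equal(sum(gp$value), 100, tolerance = 0.01)
  # zero site total: all flagged
  gp0 <- glycan_profile(fake_quant(rep(0, nrow(prof_comp)),
                                   found = rep(FALSE, nrow(prof_comp)),
                                   ids = prof_comp$component_id), prof_comp)
  expect_true(all(!gp0$defined))
})

test_that("coverage maps count residues and recovery classes exactly", {
  ch <- toy_chains()
  peps <- digest_chains(ch, max_missed = 1)
  comp <- build_component_table(peptides = peps, chains = ch)
  q <- fake_quant(rep(1000, nrow(comp)), ids = comp$component_id)
  cov <- coverage_map(q, comp, ch)
  expect_equal(cov$summary$coverage_pct, c(100, 100))
  # no peptides: zero coverage, everything in the lowest class
  cov0 <- coverage_map(fake_quant(numeric(0), ids = character(0)), comp, ch)
  expect_equal(cov0$summary$coverage_pct, c(0, 0))
  expect_true(all(cov0$residues$class == "<=1%"))
  # removing the only peptide spanning a stretch lowers coverage by its length
  lc <- ch[2, ]
  lc_pep <- digest_chains(lc, max_missed = 0)
  comp_lc <- build_component_table(peptides = lc_pep, chains = lc)
  drop_id <- comp_lc$component_id[comp_lc$sequence == "LLIYWASTR"]
  kept <- comp_lc[comp_lc$component_id != drop_id, ]
  cov1 <- coverage_map(fake_quant(rep(1, nrow(kept)), ids = kept$component_id),
                       kept, lc)
  expect_equal(cov1$summary$coverage_pct,
               100 * (nchar(lc$sequence) - 9) / nchar(lc$sequence))
})

test_that("digestion QC rates are area-weighted shares", {
  comp <- fake_components()
  q <- fake_quant(c(0, 70, 30, 0))
  expect_equal(missed_cleavage_rate(q, comp)$rate_pct, 30.0)
  # all area on fully cleaved peptides
  expect_equal(missed_cleavage_rate(fake_quant(c(10, 90, 0, 0)), comp)$rate_pct, 0)
  comp$specific[1] <- FALSE
  expect_equal(nonspecific_rate(fake_quant(c(3, 97, 0, 0)), comp)$rate_pct, 3.0)
  expect_equal(nonspecific_rate(fake_quant(c(3, 97, 0, 0) * 10), comp)$rate_pct, 3.0)
})

test_that("Venn membership partitions the union across laboratories", {
  p <- function(seqs) tibble::tibble(sequence = seqs, modification = "none",
                                     observed_mass = mono_mass(seqs))
  same <- p(c("DTLMISR", "EEQYNSTYR", "QVTLR"))
  v <- venn_membership(list(A = same, B = same, C = same))
  expect_equal(v$region, "A&B&C")
  expect_equal(v$count, 3)
  extra <- p(c("DTLMISR", "EEQYNSTYR", "QVTLR", "SLSLSPGK"))
  v2 <- venn_membership(list(A = same, B = extra))
  expect_equal(v2$count[v2$region == "B"], 1)
  expect_equal(sum(v2$count), 4)
  expect_error(venn_membership(rep(list(same), 5)), "2 to 4")
})
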