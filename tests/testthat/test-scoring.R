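oct <- heterospec_octet()
desired <- heterospec_desired_pairs()

octet_classes <- function() {
  ids <- names(oct)
  desired_keys <- paste(desired[, 1], desired[, 2])
  half1 <- c("1", "2", "3", "4")
  out <- NULL
  for (i in seq_along(ids)) {
    for (j in seq.int(i, length(ids))) {
      a <- ids[i]; b <- ids[j]
      cls <- if (a == b) "homodimer"
        else if (paste(a, b) %in% desired_keys) "desired"
        else if ((a %in% half1) == (b %in% half1)) "intrapair"
        else "interpair"
      out <- rbind(out, data.frame(a = a, b = b, class = cls))
    }
  }
  out
}

test_that("the free-energy identity suite holds over all 36 octet pairs", {
  cls <- octet_classes()
  cs <- mapply(function(a, b) delta_g_core(oct[[a]], oct[[b]]), cls$a, cls$b)
  es <- mapply(function(a, b) delta_g_electrostatic(oct[[a]], oct[[b]]),
               cls$a, cls$b)
  expect_equal(sum(cls$class == "desired"), 4)
  expect_equal(sum(cls$class == "homodimer"), 8)
  expect_equal(sum(cls$class == "intrapair"), 8)
  expect_equal(sum(cls$class == "interpair"), 16)

  expect_true(all(abs(cs[cls$class == "desired"] - (-23.2)) < 1e-9))
  expect_true(all(abs(es[cls$class == "desired"] - (-9.6)) < 1e-9))
  # homodimers keep the desired core; instability is purely electrostatic
  expect_true(all(abs(cs[cls$class == "homodimer"] - (-23.2)) < 1e-9))
  ddg_es_homo <- es[cls$class == "homodimer"] - (-9.6)
  expect_true(all(ddg_es_homo >= 7.2 - 1e-9 & ddg_es_homo <= 12.8 + 1e-9))
  expect_equal(min(ddg_es_homo), 7.2, tolerance = 1e-9)
  expect_equal(max(ddg_es_homo), 12.8, tolerance = 1e-9)
  # core penalties by off-target class
  expect_true(all(abs(cs[cls$class == "intrapair"] - (-23.2) - 21.2) < 1e-9))
  expect_true(all(abs(cs[cls$class == "interpair"] - (-23.2) - 10.6) < 1e-9))
  # heterodimeric off-target electrostatics
  ddg_es_het <- es[cls$class %in% c("intrapair", "interpair")] - (-9.6)
  expect_true(all(ddg_es_het >= 3.6 - 1e-9 & ddg_es_het <= 6.4 + 1e-9))
  expect_equal(range(ddg_es_het), c(3.6, 6.4), tolerance = 1e-9)
})

test_that("free-energy sums equal brute-force per-pair lookups on random peptides", {
  set.seed(101)
  tab <- pair_score_table(default_missing = "zero")
  lookup <- function(pairs, t) {
    s <- 0
    for (k in seq_len(nrow(pairs))) {
      key1 <- paste0(pairs$resA[k], pairs$resB[k])
      key2 <- paste0(pairs$resB[k], pairs$resA[k])
      v <- t[key1]
      if (is.na(v)) v <- t[key2]
      if (is.na(v)) v <- 0
      s <- s + v
    }
    s
  }
  core_named <- c(II = -9.2, NN = -2.4, NI = -0.5, IN = -0.5)
  el_named <- c(EK = -1.2, KE = -1.2, EE = 0.4, KK = -0.3)
  for (rep in 1:15) {
    pA <- random_registered_peptide(4, id = "A")
    pB <- random_registered_peptide(4, id = "B")
    expect_equal(delta_g_core(pA, pB, tab),
                 unname(lookup(parallel_core_pairs(pA, pB), core_named)))
    expect_equal(delta_g_electrostatic(pA, pB, tab),
                 unname(lookup(parallel_electrostatic_pairs(pA, pB), el_named)))
    expect_equal(delta_g_electrostatic(pA, pB, tab, "antiparallel"),
                 unname(lookup(antiparallel_electrostatic_pairs(pA, pB), el_named)))
  }
})

test_that("swapping one attractive E-K contact applies the footnote deltas", {
  # one complete heptad, all-E g/e on one chain, all-K on the other
  base_a <- assign_register("EIAALEA", id = "a")
  base_b <- assign_register("KIAALKA", id = "b")
  dg0 <- delta_g_electrostatic(base_a, base_b)
  # K -> E at chain b's e position turns one E-K contact into E-E: +1.6
  b_ee <- assign_register("KIAALEA", id = "b2")
  expect_equal(delta_g_electrostatic(base_a, b_ee) - dg0, 1.6, tolerance = 1e-9)
  # E -> K at chain a's g position turns one E-K contact into K-K: +0.9
  a_kk <- assign_register("KIAALEA", id = "a2")
  expect_equal(delta_g_electrostatic(a_kk, base_b) - dg0, 0.9, tolerance = 1e-9)
  # direct table deltas
  el <- default_electro_scores()
  expect_equal(unname(el["EE"] - el["EK"]), 1.6)
  expect_equal(unname(el["KK"] - el["EK"]), 0.9)
})

test_that("missing-pair policy distinguishes error and permissive modes", {
  pA <- assign_register("RIAALRA", id = "r1")  # Arg at g/e is untabulated
  pB <- assign_register("EIAALEA", id = "e1")
  expect_error(delta_g_electrostatic(pA, pB), "no electrostatic score")
  permissive <- pair_score_table(default_missing = "zero")
  expect_equal(delta_g_electrostatic(pA, pB, permissive), 0)
  expect_equal(delta_g_core(pA, pB, permissive), -9.2)
})

test_that("helicity scoring averages non-cap residues and caches per peptide", {
  oct1 <- oct[["1"]]
  expect_equal(helicity_score(oct1, oct1), helicity_score(oct1, oct1))
  # identical chains: pair score equals the single-chain mean
  tab <- default_helicity_table()
  core_res <- strsplit(oct1$sequence, "")[[1]][strsplit(oct1$register, "")[[1]] != "-"]
  expect_equal(helicity_score(oct1, oct1), mean(tab[core_res]))
  # all-ones table scores 1 for any pair
  ones <- setNames(rep(1, 20), names(tab))
  expect_equal(helicity_score(oct[["1"]], oct[["5"]], ones), 1)
  # random peptide against direct averaging oracle
  set.seed(5)
  for (rep in 1:10) {
    pA <- random_registered_peptide(3, id = "A")
    pB <- random_registered_peptide(4, id = "B")
    resA <- strsplit(pA$sequence, "")[[1]][strsplit(pA$register, "")[[1]] != "-"]
    resB <- strsplit(pB$sequence, "")[[1]][strsplit(pB$register, "")[[1]] != "-"]
    expect_equal(helicity_score(pA, pB), mean(tab[c(resA, resB)]))
  }
  # caps never contribute
  with_cap <- assign_register("PPEIAALEPP", cap_prefix_len = 2,
                              cap_suffix_len = 2, id = "cap")
  no_cap <- assign_register("EIAALE", id = "nocap")
  expect_equal(helicity_score(with_cap, with_cap),
               helicity_score(no_cap, no_cap))
  expect_error(helicity_score(no_cap, no_cap, tab[-(1:5)]),
               "missing from the helicity table")
})

test_that("the Tm model is linear in its terms and symmetric in its arguments", {
  cs_only <- tm_model(w_hp = 0, w_cs = 1, w_es = 0, intercept = 0)
  expect_equal(predict_tm(oct[["1"]], oct[["2"]], cs_only), -23.2)
  es_only <- tm_model(w_hp = 0, w_cs = 0, w_es = 1, intercept = 0)
  expect_equal(predict_tm(oct[["1"]], oct[["2"]], es_only), -9.6)
  m <- default_tm_model()
  for (i in 1:8) {
    for (j in i:8) {
      a <- oct[[as.character(i)]]; b <- oct[[as.character(j)]]
      expect_equal(predict_tm(a, b, m), predict_tm(b, a, m))
    }
  }
  expect_error(tm_model(w_hp = NA, w_cs = 1, w_es = 1, intercept = 0), "finite")
})
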