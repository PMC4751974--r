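test_that("register assignment annotates the worked-example layout correctly", {
  p1 <- assign_register("ASENAALEAKNAALKYKIAALKAEIAALEGAP", start_letter = "g",
                        cap_prefix_len = 2, cap_suffix_len = 3, id = "1")
  expect_equal(unname(residues_at(p1, "a")), c("N", "N", "I", "I"))
  expect_equal(unname(residues_at(p1, "g")), c("E", "K", "K", "E"))
  expect_equal(unname(residues_at(p1, "e")), c("E", "K", "K", "E"))
  expect_equal(unname(residues_at(p1, "d")), c("L", "L", "L", "L"))
  expect_equal(substr(p1$register, 1, 2), "--")
  expect_equal(substr(p1$register, 30, 32), "---")
})

test_that("single heptad and malformed inputs behave as specified", {
  # a-start register has its g after its e, so no complete g..e span exists
  expect_warning(p <- registered_peptide("x", "AEAALEK", "abcdefg"),
                 "g\\.\\.e span")
  expect_equal(p$register, "abcdefg")
  expect_error(assign_register("ABCDEFG"), "invalid residue")
  expect_error(registered_peptide("x", "AAAA", "gabc0"), "length")
  expect_error(registered_peptide("x", "AAAA", "gacb"), "cyclic")
  # no complete g..e span -> warning, not error
  expect_warning(assign_register("AEAALEK", start_letter = "a"), "g\\.\\.e span")
})

test_that("core and electrostatic pair counts and contents match the design", {
  oct <- heterospec_octet()
  core12 <- parallel_core_pairs(oct[["1"]], oct[["2"]])
  expect_equal(sort(paste0(core12$resA, core12$resB)), c("II", "II", "NN", "NN"))
  core13 <- parallel_core_pairs(oct[["1"]], oct[["3"]])
  expect_true(all(paste0(core13$resA, core13$resB) %in% c("NI", "IN")))
  expect_equal(nrow(core13), 4)
  core15 <- parallel_core_pairs(oct[["1"]], oct[["5"]])
  expect_equal(sort(paste0(core15$resA, core15$resB)), c("II", "IN", "NI", "NN"))

  el12 <- parallel_electrostatic_pairs(oct[["1"]], oct[["2"]])
  expect_equal(nrow(el12), 8)
  expect_true(all(paste0(el12$resA, el12$resB) %in% c("EK", "KE")))
  el11 <- parallel_electrostatic_pairs(oct[["1"]], oct[["1"]])
  expect_true(all(paste0(el11$resA, el11$resB) %in% c("EE", "KK")))
  el13 <- parallel_electrostatic_pairs(oct[["1"]], oct[["3"]])
  attractive <- paste0(el13$resA, el13$resB) %in% c("EK", "KE")
  expect_equal(sum(attractive), 4)
  expect_equal(sum(!attractive), 4)
})

test_that("antiparallel electrostatic enumeration distinguishes the octet halves", {
  oct <- heterospec_octet()
  ap5 <- antiparallel_electrostatic_pairs(oct[["5"]], oct[["5"]])
  expect_equal(nrow(ap5), 8)
  expect_true(all(paste0(ap5$resA, ap5$resB) %in% c("EK", "KE")))
  ap3 <- antiparallel_electrostatic_pairs(oct[["3"]], oct[["3"]])
  expect_true(all(paste0(ap3$resA, ap3$resB) == "EE"))
  # peptide 1's palindromic E,K,K,E charge pattern makes every antiparallel
  # homodimer contact repulsive -- in particular not fully complementary
  ap1 <- antiparallel_electrostatic_pairs(oct[["1"]], oct[["1"]])
  expect_true(all(paste0(ap1$resA, ap1$resB) %in% c("EE", "KK")))
  expect_true(all(vapply(oct[5:8], antiparallel_complementary, logical(1))))
  expect_false(any(vapply(oct[1:4], antiparallel_complementary, logical(1))))
})

test_that("pair lists are symmetric in their arguments for all 36 octet pairs", {
  oct <- heterospec_octet()
  ids <- names(oct)
  for (i in seq_along(ids)) {
    for (j in seq.int(i, length(ids))) {
      a <- oct[[ids[i]]]; b <- oct[[ids[j]]]
      for (f in list(parallel_core_pairs, parallel_electrostatic_pairs,
                     antiparallel_electrostatic_pairs)) {
        ab <- f(a, b)
        ba <- f(b, a)
        swapped <- data.frame(posA = ba$posB, posB = ba$posA,
                              resA = ba$resB, resB = ba$resA)
        expect_equal(pair_multiset(ab[, c("posA", "posB", "resA", "resB")]),
                     pair_multiset(swapped))
      }
    }
  }
})

test_that("pair enumeration agrees with a brute-force index-scan oracle", {
  set.seed(42)
  for (rep in 1:25) {
    pA <- random_registered_peptide(sample(2:5, 1), id = "A")
    pB <- random_registered_peptide(sample(2:5, 1), id = "B")
    cols <- c("posA", "posB", "resA", "resB")
    expect_equal(
      pair_multiset(suppressWarnings(parallel_core_pairs(pA, pB))[, cols]),
      pair_multiset(oracle_core_pairs(pA, pB)))
    expect_equal(
      pair_multiset(suppressWarnings(parallel_electrostatic_pairs(pA, pB))[, cols]),
      pair_multiset(oracle_parallel_electro(pA, pB)))
    expect_equal(
      pair_multiset(suppressWarnings(antiparallel_electrostatic_pairs(pA, pB))[, cols]),
      pair_multiset(oracle_antiparallel_electro(pA, pB)))
  }
})

test_that("count conservation holds for four-heptad chains in both orientations", {
  set.seed(7)
  for (rep in 1:10) {
    pA <- random_registered_peptide(4, id = "A")
    pB <- random_registered_peptide(4, id = "B")
    expect_equal(nrow(parallel_core_pairs(pA, pB)), 4)
    expect_equal(nrow(parallel_electrostatic_pairs(pA, pB)), 8)
    expect_equal(nrow(antiparallel_electrostatic_pairs(pA, pB)), 8)
  }
})

test_that("unequal chains are truncated to the shared heptads with a warning", {
  pA <- assign_register(strrep("ENAALEA", 4), start_letter = "g", id = "long")
  pB <- assign_register(substr(strrep("ENAALEA", 4), 1, 13), start_letter = "g",
                        id = "short")
  expect_warning(cp <- parallel_core_pairs(pA, pB), "unequal")
  expect_equal(nrow(cp), 2)
  expect_warning(ep <- parallel_electrostatic_pairs(pA, pB), "unequal")
  expect_equal(nrow(ep), 4)  # two shared heptads, two contacts each
})
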