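# A hand-built six-peptide instance with two clean orthogonal 4-peptide sets
hand_instance <- function() {
  ids <- c("A", "B", "C", "D", "E", "F")
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m["A", "B"] <- m["B", "A"] <- 75
  m["C", "D"] <- m["D", "C"] <- 80
  m["E", "F"] <- m["F", "E"] <- 72
  m[cbind(ids, ids)] <- c(-5, 0, 5, -10, 2, 8)
  # cross-talk: E is promiscuous with A, F with C
  m["A", "E"] <- m["E", "A"] <- 35
  m["C", "F"] <- m["F", "C"] <- 25
  m
}

test_that("find_pairs on the hand-built instance accepts exactly the clean sets", {
  m <- hand_instance()
  crit <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 20,
                          min_delta_tm_pairs = 50)
  x <- toy_interactome(m, crit$min_desired_tm)
  sets <- find_pairs(x, crit)
  # A-B + C-D passes (all off-targets <= 5, delta 75 - 5 = 70); sets with
  # E-F fail on the A-E or C-F cross-talk off-target
  expect_length(sets, 1)
  expect_equal(sets[[1]]$peptides, c("A", "B", "C", "D"))
  expect_equal(sets[[1]]$min_desired_tm, 75)
  expect_equal(sets[[1]]$offtarget_max_tm, 5)
  expect_equal(sets[[1]]$delta_tm, 70)
  # each 4-peptide set enumerates exactly 8 off-targets over 10 pairings
  expect_equal(nrow(sets[[1]]$desired), 2)
})

test_that("candidate interactions sharing a peptide are never combined", {
  ids <- c("A", "B", "C")
  m <- matrix(-10, 3, 3, dimnames = list(ids, ids))
  m["A", "B"] <- m["B", "A"] <- 90
  m["A", "C"] <- m["C", "A"] <- 90
  crit <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 20,
                          min_delta_tm_pairs = 0)
  sets <- find_pairs(toy_interactome(m, 70), crit)
  expect_length(sets, 0)
})

test_that("find_pairs equals exhaustive enumeration on random toy instances", {
  for (seed in 1:8) {
    set.seed(seed)
    ids <- LETTERS[1:sample(6:10, 1)]
    m <- random_tm_matrix(ids)
    crit <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 30,
                            min_delta_tm_pairs = 35)
    x <- toy_interactome(m, crit$min_desired_tm)
    got <- find_pairs(x, crit)
    want <- oracle_find_pairs(m, crit)
    expect_setequal(vapply(got, set_signature, character(1)),
                    vapply(want, oracle_signature, character(1)))
  }
})

test_that("find_quadruples equals exhaustive enumeration on 12-peptide instances", {
  found_any <- FALSE
  for (seed in 1:6) {
    set.seed(seed)
    ids <- LETTERS[1:12]
    m <- matched_tm_matrix(ids)
    crit <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_quads = 40,
                            min_delta_tm_quads = 25,
                            max_offtarget_tm_pairs = 40,
                            min_delta_tm_pairs = 25)
    x <- toy_interactome(m, crit$min_desired_tm)
    pairs <- find_pairs(x, crit)
    got <- find_quadruples(pairs, x, crit)
    want <- oracle_find_quadruples(m, crit)
    expect_setequal(vapply(got, set_signature, character(1)),
                    vapply(want, oracle_signature, character(1)))
    found_any <- found_any || length(got) > 0
  }
  expect_true(found_any)  # the comparison must exercise non-empty outputs
})

test_that("every emitted set re-verifies against an independent checker", {
  set.seed(99)
  ids <- LETTERS[1:10]
  m <- random_tm_matrix(ids, hot_frac = 0.35)
  crit <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 35,
                          min_delta_tm_pairs = 30,
                          max_offtarget_tm_quads = 45, min_delta_tm_quads = 20)
  x <- toy_interactome(m, crit$min_desired_tm)
  pairs <- find_pairs(x, crit)
  quads <- find_quadruples(pairs, x, crit)
  check <- function(s, max_off, min_delta, n_pep, n_off) {
    expect_length(s$peptides, n_pep)
    expect_false(anyDuplicated(c(s$desired$idA, s$desired$idB)) > 0)
    off <- NULL
    for (p in seq_along(s$peptides)) for (q in seq.int(p, length(s$peptides))) {
      a <- s$peptides[p]; b <- s$peptides[q]
      if (!any(s$desired$idA == a & s$desired$idB == b)) {
        off <- c(off, m[a, b])
      }
    }
    expect_length(off, n_off)
    expect_true(all(off <= max_off))
    des <- mapply(function(a, b) m[a, b], s$desired$idA, s$desired$idB)
    expect_true(all(des >= crit$min_desired_tm))
    expect_gte(min(des) - max(off), min_delta)
    expect_equal(s$delta_tm, min(des) - max(off))
  }
  expect_gt(length(pairs), 0)
  for (s in pairs) check(s, crit$max_offtarget_tm_pairs,
                         crit$min_delta_tm_pairs, 4, 8)
  for (s in quads) check(s, crit$max_offtarget_tm_quads,
                         crit$min_delta_tm_quads, 8, 32)
})

test_that("tightening thresholds never adds sets; loosening never removes them", {
  for (seed in 1:5) {
    set.seed(seed * 17)
    ids <- LETTERS[1:9]
    m <- random_tm_matrix(ids, hot_frac = 0.3)
    base <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 30,
                            min_delta_tm_pairs = 30)
    tight <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 20,
                             min_delta_tm_pairs = 30)
    loose <- screen_criteria(min_desired_tm = 70, max_offtarget_tm_pairs = 45,
                             min_delta_tm_pairs = 30)
    x <- toy_interactome(m, 70)
    sig <- function(crit) vapply(find_pairs(x, crit), set_signature, character(1))
    s_base <- sig(base); s_tight <- sig(tight); s_loose <- sig(loose)
    expect_true(all(s_tight %in% s_base))
    expect_true(all(s_base %in% s_loose))
  }
})

test_that("rank_sets orders by desired Tm, then separation, deterministically", {
  mk <- function(tmA, tmB, off, ids) {
    desired <- data.frame(idA = ids[c(1, 3)], idB = ids[c(2, 4)],
                          tm = c(tmA, tmB), stringsAsFactors = FALSE)
    heterospec:::new_orthogonal_set(desired, off)
  }
  s1 <- mk(80, 75, 30, c("A", "B", "C", "D"))  # min 75, delta 45
  s2 <- mk(80, 75, 35, c("E", "F", "G", "H"))  # min 75, delta 40
  s3 <- mk(90, 85, 60, c("I", "J", "K", "L"))  # min 85, delta 25
  ranked <- rank_sets(list(s2, s1, s3))
  expect_equal(vapply(ranked, function(s) s$peptides[1], character(1)),
               c("I", "A", "E"))
  # permutation invariance
  ranked2 <- rank_sets(list(s1, s3, s2))
  expect_identical(vapply(ranked2, set_signature, character(1)),
                   vapply(ranked, set_signature, character(1)))
  expect_identical(rank_sets(list(s1)), list(s1))
})
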