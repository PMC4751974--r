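# Independent brute-force oracles, deliberately written as plain index scans
# so they share no code with the package's span-based enumeration.

# Random peptide on the library's register layout: random caps, random
# residues drawn from the scored alphabet so the default tables cover them.
random_registered_peptide <- function(n_heptads = 4L, id = "rnd",
                                      alphabet = c("E", "K", "N", "I", "A", "L")) {
  cap_pre <- sample(0:3, 1L)
  cap_suf <- sample(0:3, 1L)
  n_core <- n_heptads * 7L - 1L  # g-start, e-last
  n <- cap_pre + n_core + cap_suf
  seqs <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
  assign_register(seqs, start_letter = "g",
                  cap_prefix_len = cap_pre, cap_suffix_len = cap_suf, id = id)
}

oracle_core_pairs <- function(pA, pB) {
  rA <- strsplit(pA$register, "")[[1]]
  rB <- strsplit(pB$register, "")[[1]]
  sA <- strsplit(pA$sequence, "")[[1]]
  sB <- strsplit(pB$sequence, "")[[1]]
  ia <- which(rA == "a")
  ib <- which(rB == "a")
  out <- NULL
  for (i in seq_along(ia)) {
    for (j in seq_along(ib)) {
      if (i == j && i <= min(length(ia), length(ib))) {
        out <- rbind(out, data.frame(posA = ia[i], posB = ib[j],
                                     resA = sA[ia[i]], resB = sB[ib[j]]))
      }
    }
  }
  if (is.null(out)) data.frame(posA = integer(), posB = integer(),
                               resA = character(), resB = character())
  else out
}

# g of A pairs with the partner's e five residues C-terminal, and vice versa,
# restricted to complete g..e spans present in both chains.
oracle_parallel_electro <- function(pA, pB) {
  rA <- strsplit(pA$register, "")[[1]]
  rB <- strsplit(pB$register, "")[[1]]
  sA <- strsplit(pA$sequence, "")[[1]]
  sB <- strsplit(pB$sequence, "")[[1]]
  span <- function(r) {
    g <- which(r == "g")
    g[g + 5 <= length(r) & r[pmin(g + 5, length(r))] == "e"]
  }
  gA <- span(rA); gB <- span(rB)
  n <- min(length(gA), length(gB))
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out,
      data.frame(posA = gA[k], posB = gB[k] + 5,
                 resA = sA[gA[k]], resB = sB[gB[k] + 5]),
      data.frame(posA = gA[k] + 5, posB = gB[k],
                 resA = sA[gA[k] + 5], resB = sB[gB[k]]))
  }
  if (is.null(out)) data.frame(posA = integer(), posB = integer(),
                               resA = character(), resB = character())
  else out
}

oracle_antiparallel_electro <- function(pA, pB) {
  rA <- strsplit(pA$register, "")[[1]]
  rB <- strsplit(pB$register, "")[[1]]
  sA <- strsplit(pA$sequence, "")[[1]]
  sB <- strsplit(pB$sequence, "")[[1]]
  span <- function(r) {
    g <- which(r == "g")
    g[g + 5 <= length(r) & r[pmin(g + 5, length(r))] == "e"]
  }
  gA <- span(rA); gB <- span(rB)
  n <- min(length(gA), length(gB))
  out <- NULL
  for (k in seq_len(n)) {
    m <- n + 1 - k
    out <- rbind(out,
      data.frame(posA = gA[k], posB = gB[m],
                 resA = sA[gA[k]], resB = sB[gB[m]]),
      data.frame(posA = gA[k] + 5, posB = gB[m] + 5,
                 resA = sA[gA[k] + 5], resB = sB[gB[m] + 5]))
  }
  if (is.null(out)) data.frame(posA = integer(), posB = integer(),
                               resA = character(), resB = character())
  else out
}

# Canonical multiset representation of a pair list for comparisons that
# ignore row order and A/B member order.
pair_multiset <- function(df) {
  sort(apply(df, 1, function(r) {
    a <- paste0(r[["posA"]], r[["resA"]])
    b <- paste0(r[["posB"]], r[["resB"]])
    paste(sort(c(a, b)), collapse = "~")
  }))
}

# Toy interactome with hand-set (or random) Tm values; peptide entries are
# placeholders because the searches only consult the interaction table.
toy_interactome <- function(tm_matrix, min_desired_tm) {
  ids <- rownames(tm_matrix)
  idx <- which(upper.tri(tm_matrix, diag = TRUE), arr.ind = TRUE)
  interactions <- data.frame(
    idA = ids[idx[, 1]], idB = ids[idx[, 2]],
    tm = tm_matrix[idx], stringsAsFactors = FALSE
  )
  interactions$stored <- interactions$tm >= min_desired_tm
  interactions <- interactions[order(interactions$idA, interactions$idB), ]
  rownames(interactions) <- NULL
  structure(
    list(peptides = stats::setNames(vector("list", length(ids)), ids),
         interactions = interactions,
         provenance = list(model = "toy")),
    class = "interactome"
  )
}

random_tm_matrix <- function(ids, hot_frac = 0.2, min_desired = 70) {
  n <- length(ids)
  m <- matrix(runif(n * n, -20, 40), n, n, dimnames = list(ids, ids))
  hot <- which(upper.tri(m), arr.ind = TRUE)
  hot <- hot[sample(nrow(hot), max(2L, round(nrow(hot) * hot_frac))), , drop = FALSE]
  m[hot] <- runif(nrow(hot), min_desired, min_desired + 20)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Hot interactions planted on a random perfect matching, so that disjoint
# candidate pairs (and hence quadruples) actually occur.
matched_tm_matrix <- function(ids, p_hot = 0.8, min_desired = 70) {
  n <- length(ids)
  m <- matrix(runif(n * n, -20, 40), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  matching <- matrix(sample(ids), ncol = 2)
  for (k in seq_len(nrow(matching))) {
    if (runif(1) < p_hot) {
      tm <- runif(1, min_desired, min_desired + 20)
      m[matching[k, 1], matching[k, 2]] <- tm
      m[matching[k, 2], matching[k, 1]] <- tm
    }
  }
  m
}

# Exhaustive, unpruned search for orthogonal 4-peptide sets.
oracle_find_pairs <- function(m, criteria) {
  ids <- rownames(m)
  cand <- NULL
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b && m[a, b] >= criteria$min_desired_tm) {
      cand <- rbind(cand, data.frame(a = ids[a], b = ids[b]))
    }
  }
  out <- list()
  if (is.null(cand) || nrow(cand) < 2) return(out)
  for (i in seq_len(nrow(cand) - 1)) for (j in seq.int(i + 1, nrow(cand))) {
    ids4 <- c(cand$a[i], cand$b[i], cand$a[j], cand$b[j])
    if (length(unique(ids4)) != 4) next
    desired_tm <- c(m[cand$a[i], cand$b[i]], m[cand$a[j], cand$b[j]])
    off <- c(
      m[cand$a[i], cand$a[i]], m[cand$b[i], cand$b[i]],
      m[cand$a[j], cand$a[j]], m[cand$b[j], cand$b[j]],
      m[cand$a[i], cand$a[j]], m[cand$a[i], cand$b[j]],
      m[cand$b[i], cand$a[j]], m[cand$b[i], cand$b[j]]
    )
    if (max(off) > criteria$max_offtarget_tm_pairs) next
    if (min(desired_tm) - max(off) < criteria$min_delta_tm_pairs) next
    out[[length(out) + 1]] <- list(
      peptides = sort(ids4),
      desired = sort(c(paste(sort(c(cand$a[i], cand$b[i])), collapse = "-"),
                       paste(sort(c(cand$a[j], cand$b[j])), collapse = "-")))
    )
  }
  out
}

# Exhaustive search for orthogonal 8-peptide sets over oracle pair results.
oracle_find_quadruples <- function(m, criteria) {
  pcrit <- criteria
  pairs <- oracle_find_pairs(m, pcrit)
  out <- list()
  seen <- character(0)
  if (length(pairs) < 2) return(out)
  for (i in seq_len(length(pairs) - 1)) for (j in seq.int(i + 1, length(pairs))) {
    a <- pairs[[i]]; b <- pairs[[j]]
    if (length(intersect(a$peptides, b$peptides)) > 0) next
    desired <- sort(c(a$desired, b$desired))
    key <- paste(desired, collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    ids8 <- sort(c(a$peptides, b$peptides))
    desired_tm <- vapply(strsplit(desired, "-"),
                         function(d) m[d[1], d[2]], numeric(1))
    off <- NULL
    for (p in seq_along(ids8)) for (q in seq.int(p, length(ids8))) {
      pr <- paste(c(ids8[p], ids8[q]), collapse = "-")
      if (!(pr %in% desired)) off <- c(off, m[ids8[p], ids8[q]])
    }
    if (max(off) > criteria$max_offtarget_tm_quads) next
    if (min(desired_tm) - max(off) < criteria$min_delta_tm_quads) next
    out[[length(out) + 1]] <- list(peptides = ids8, desired = desired)
  }
  out
}

set_signature <- function(s) {
  paste(sort(paste0(s$desired$idA, "-", s$desired$idB)), collapse = ";")
}

oracle_signature <- function(s) paste(s$desired, collapse = ";")
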