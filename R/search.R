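new_orthogonal_set <- function(desired, tm_all_off) {
  desired <- desired[order(desired$idA, desired$idB), , drop = FALSE]
  rownames(desired) <- NULL
  min_desired <- min(desired$tm)
  max_off <- max(tm_all_off)
  structure(
    list(desired = desired,
         peptides = sort(unique(c(desired$idA, desired$idB))),
         offtarget_max_tm = max_off,
         min_desired_tm = min_desired,
         delta_tm = min_desired - max_off),
    class = "orthogonal_set"
  )
}

#' @export
print.orthogonal_set <- function(x, ...) {
  cat("<orthogonal_set> {", paste(x$peptides, collapse = ","), "}: ",
      nrow(x$desired), " desired (min Tm ", round(x$min_desired_tm, 1),
      "), max off-target ", round(x$offtarget_max_tm, 1),
      ", delta ", round(x$delta_tm, 1), "\n", sep = "")
  invisible(x)
}

# All unordered pairings over a peptide id set, homodimers included.
all_pairings <- function(ids) {
  ids <- sort(ids)
  n <- length(ids)
  i <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L) + i - 1L
  data.frame(idA = ids[i], idB = ids[j], stringsAsFactors = FALSE)
}

pair_key <- function(idA, idB) {
  ifelse(idA <= idB, paste0(idA, "\r", idB), paste0(idB, "\r", idA))
}

# Evaluate one candidate set: desired interactions (data frame idA/idB/tm)
# against the full mini-interactome of its peptides. Homodimers are
# re-checked here even though import filtering bounds them, so the checker
# is self-contained.
evaluate_set <- function(x, desired, max_offtarget_tm, min_delta_tm) {
  ids <- unique(c(desired$idA, desired$idB))
  pairings <- all_pairings(ids)
  is_desired <- pair_key(pairings$idA, pairings$idB) %in%
    pair_key(desired$idA, desired$idB)
  off <- pairings[!is_desired, , drop = FALSE]
  tm_off <- tm_lookup(x, off$idA, off$idB)
  if (any(tm_off > max_offtarget_tm)) return(NULL)
  set <- new_orthogonal_set(desired, tm_off)
  if (set$delta_tm < min_delta_tm) return(NULL)
  set
}

#' Find orthogonal pairs of coiled coils (4-peptide sets)
#'
#' Searches the stored candidate interactions (predicted Tm at or above
#' `criteria$min_desired_tm`) for pairs of heterodimers that are predicted
#' to be specific in each other's presence. Candidate interactions sharing a
#' peptide are skipped without scoring (cross-talk is certain). For each
#' remaining combination the full 4-peptide mini-interactome (10 pairings: 2
#' desired, 4 homodimers, 4 cross heterodimers) is checked: every off-target
#' must stay at or below `criteria$max_offtarget_tm_pairs` and the
#' worst-case separation `min(desired Tm) - max(off-target Tm)` must reach
#' `criteria$min_delta_tm_pairs`.
#'
#' @param x An [screen_interactome()] result.
#' @param criteria A [screen_criteria()].
#' @return List of `orthogonal_set` objects (possibly empty), deduplicated
#'   by canonical peptide ordering, in [rank_sets()] order.
#' @export
find_pairs <- function(x, criteria = screen_criteria()) {
  stopifnot(inherits(x, "interactome"), inherits(criteria, "screen_criteria"))
  cand <- x$interactions[x$interactions$stored & x$interactions$idA != x$interactions$idB, ,
                         drop = FALSE]
  out <- list()
  n <- nrow(cand)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      a <- cand[i, ]
      for (j in seq.int(i + 1L, n)) {
        b <- cand[j, ]
        ids <- c(a$idA, a$idB, b$idA, b$idB)
        if (anyDuplicated(ids)) next  # shared peptide: certain cross-talk
        desired <- data.frame(idA = c(a$idA, b$idA), idB = c(a$idB, b$idB),
                              tm = c(a$tm, b$tm), stringsAsFactors = FALSE)
        set <- evaluate_set(x, desired, criteria$max_offtarget_tm_pairs,
                            criteria$min_delta_tm_pairs)
        if (!is.null(set)) out[[length(out) + 1L]] <- set
      }
    }
  }
  rank_sets(out)
}

#' Find orthogonal quadruples of coiled coils (8-peptide sets)
#'
#' Combines 4-peptide sets from [find_pairs()] pairwise. Combinations
#' sharing any peptide are skipped; otherwise the full 8-peptide
#' mini-interactome (36 pairings: 4 desired, 8 homodimers, 24 cross
#' heterodimers — 32 off-targets) is checked against
#' `criteria$max_offtarget_tm_quads` and `criteria$min_delta_tm_quads`.
#'
#' @param pairsets List of `orthogonal_set` objects from [find_pairs()].
#' @param x The [screen_interactome()] result the sets were found in.
#' @param criteria A [screen_criteria()].
#' @return List of 8-peptide `orthogonal_set` objects in [rank_sets()]
#'   order, deduplicated by their four desired interactions.
#' @export
find_quadruples <- function(pairsets, x, criteria = screen_criteria()) {
  stopifnot(inherits(x, "interactome"), inherits(criteria, "screen_criteria"))
  out <- list()
  seen <- character(0L)
  n <- length(pairsets)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- pairsets[[i]]; b <- pairsets[[j]]
        if (length(intersect(a$peptides, b$peptides)) > 0L) next
        desired <- rbind(a$desired, b$desired)
        key <- paste(sort(pair_key(desired$idA, desired$idB)), collapse = ";")
        if (key %in% seen) next
        seen <- c(seen, key)
        set <- evaluate_set(x, desired, criteria$max_offtarget_tm_quads,
                            criteria$min_delta_tm_quads)
        if (!is.null(set)) out[[length(out) + 1L]] <- set
      }
    }
  }
  rank_sets(out)
}

#' Rank orthogonal sets
#'
#' Orders sets by decreasing minimum desired Tm, then decreasing
#' desired-to-off-target separation, then lexicographically by peptide ids
#' (a deterministic tiebreak). The head of the ranking is the natural
#' selection for synthesis: the most stable desired interactions with the
#' widest specificity margin.
#'
#' @param sets List of `orthogonal_set` objects.
#' @return The same sets, reordered.
#' @export
rank_sets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  key <- vapply(sets, function(s) paste(s$peptides, collapse = ","),
                character(1L))
  ord <- order(-vapply(sets, `[[`, numeric(1L), "min_desired_tm"),
               -vapply(sets, `[[`, numeric(1L), "delta_tm"),
               key)
  sets[ord]
}

#' Tabulate orthogonal sets for reporting
#'
#' @param sets List of `orthogonal_set` objects.
#' @return Data frame with one row per set: member peptides, desired
#'   interactions with their Tm values, maximum off-target Tm, minimum
#'   desired Tm and the separation `delta_tm`.
#' @export
sets_table <- function(sets) {
  if (length(sets) == 0L) {
    return(data.frame(peptides = character(), desired = character(),
                      desired_tm = character(), offtarget_max_tm = numeric(),
                      min_desired_tm = numeric(), delta_tm = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(sets, function(s) {
    data.frame(
      peptides = paste(s$peptides, collapse = ","),
      desired = paste(paste0(s$desired$idA, "-", s$desired$idB), collapse = ";"),
      desired_tm = paste(format(s$desired$tm, trim = TRUE), collapse = ";"),
      offtarget_max_tm = s$offtarget_max_tm,
      min_desired_tm = s$min_desired_tm,
      delta_tm = s$delta_tm,
      stringsAsFactors = FALSE
    )
  }))
}
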