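#' Screening criteria
#'
#' Thresholds (degrees C) controlling the interactome screen and the
#' orthogonal-set searches. Defaults are the worked example's settings:
#' homodimers above 10 are rejected at import, desired heterodimers must
#' reach 70, off-targets within a 4-peptide set may not exceed 20 with a
#' minimum desired-to-off-target separation of 50, and within an 8-peptide
#' set 30 and 40 respectively (quadruples tolerate slightly warmer
#' off-targets because the number of constraints quadruples).
#'
#' @param max_homodimer_tm Maximum acceptable predicted homodimer Tm at
#'   import.
#' @param min_desired_tm Minimum Tm for an interaction to be stored as a
#'   candidate desired pair.
#' @param max_offtarget_tm_pairs,min_delta_tm_pairs Off-target ceiling and
#'   minimum desired-minus-off-target separation for 4-peptide sets.
#' @param max_offtarget_tm_quads,min_delta_tm_quads The same for 8-peptide
#'   sets.
#' @param antiparallel_filter If `TRUE`, also reject at import any peptide
#'   whose antiparallel homodimer has every electrostatic contact attractive
#'   (see [antiparallel_complementary()]). This sequence-based filter is
#'   independent of the Tm model's coefficients.
#' @return Object of class `screen_criteria`.
#' @export
screen_criteria <- function(max_homodimer_tm = 10,
                            min_desired_tm = 70,
                            max_offtarget_tm_pairs = 20,
                            min_delta_tm_pairs = 50,
                            max_offtarget_tm_quads = 30,
                            min_delta_tm_quads = 40,
                            antiparallel_filter = FALSE) {
  vals <- c(max_homodimer_tm, min_desired_tm, max_offtarget_tm_pairs,
            min_delta_tm_pairs, max_offtarget_tm_quads, min_delta_tm_quads)
  if (anyNA(vals)) stop("screening thresholds must not be NA")
  if (min_desired_tm <= max_offtarget_tm_pairs) {
    stop("min_desired_tm must exceed max_offtarget_tm_pairs")
  }
  structure(
    list(max_homodimer_tm = max_homodimer_tm,
         min_desired_tm = min_desired_tm,
         max_offtarget_tm_pairs = max_offtarget_tm_pairs,
         min_delta_tm_pairs = min_delta_tm_pairs,
         max_offtarget_tm_quads = max_offtarget_tm_quads,
         min_delta_tm_quads = min_delta_tm_quads,
         antiparallel_filter = isTRUE(antiparallel_filter)),
    class = "screen_criteria"
  )
}

#' Import-time sequence filter
#'
#' Applies the earliest-opportunity filters that keep the interactome within
#' useful search space: peptides whose predicted parallel homodimer Tm
#' exceeds `criteria$max_homodimer_tm` are dropped (they can never appear in
#' an orthogonal set), and, when `criteria$antiparallel_filter` is on,
#' peptides whose antiparallel homodimer is fully electrostatically
#' complementary are dropped as candidate unplanned antiparallel dimers.
#' Each peptide's helicity contribution is computed once here and cached in
#' the model.
#'
#' @param peptides List of [registered_peptide()] objects.
#' @param model A [tm_model()].
#' @param criteria A [screen_criteria()].
#' @return List with `retained` (peptide list) and `rejected` (data frame
#'   with columns `id`, `reason`, `tm_homodimer`).
#' @export
import_filter <- function(peptides, model = default_tm_model(),
                          criteria = screen_criteria()) {
  stopifnot(inherits(model, "tm_model"), inherits(criteria, "screen_criteria"))
  rejected <- data.frame(id = character(), reason = character(),
                         tm_homodimer = numeric(), stringsAsFactors = FALSE)
  if (length(peptides) == 0L) return(list(retained = list(), rejected = rejected))
  keep <- logical(length(peptides))
  for (i in seq_along(peptides)) {
    p <- peptides[[i]]
    tm_homo <- predict_tm(p, p, model)
    if (tm_homo > criteria$max_homodimer_tm) {
      rejected <- rbind(rejected, data.frame(
        id = p$id, reason = "homodimer_tm", tm_homodimer = tm_homo,
        stringsAsFactors = FALSE))
    } else if (criteria$antiparallel_filter && antiparallel_complementary(p)) {
      rejected <- rbind(rejected, data.frame(
        id = p$id, reason = "antiparallel_complementary",
        tm_homodimer = tm_homo, stringsAsFactors = FALSE))
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = peptides[keep], rejected = rejected)
}

# Vectorised per-peptide feature extraction for the fast screen path:
# a-position residues, span g/e residues and helicity sums, as matrices.
peptide_features <- function(peptides, model) {
  n_a <- vapply(peptides, function(p) length(residues_at(p, "a")), integer(1L))
  n_sp <- vapply(peptides, function(p) nrow(ge_spans(p)), integer(1L))
  if (length(unique(n_a)) > 1L || length(unique(n_sp)) > 1L) {
    return(NULL)  # heterogeneous library: fall back to the reference path
  }
  a_mat <- t(vapply(peptides, function(p) unname(residues_at(p, "a")),
                    character(n_a[[1L]])))
  g_mat <- t(vapply(peptides, function(p) {
    sp <- ge_spans(p); seq_chars(p)[sp$g]
  }, character(n_sp[[1L]])))
  e_mat <- t(vapply(peptides, function(p) {
    sp <- ge_spans(p); seq_chars(p)[sp$e]
  }, character(n_sp[[1L]])))
  hp <- vapply(peptides, function(p) {
    h <- single_chain_helicity(p, model$helicity, model$cache)
    c(h$sum, h$n)
  }, numeric(2L))
  list(a = a_mat, g = g_mat, e = e_mat,
       hp_sum = hp[1L, ], hp_n = hp[2L, ])
}

score_sum <- function(tab, keys, policy, what) {
  vals <- tab[keys]
  if (anyNA(vals)) {
    if (policy == "error") {
      stop("no ", what, " score for residue pair(s): ",
           paste(sort(unique(keys[is.na(vals)])), collapse = ", "))
    }
    vals[is.na(vals)] <- 0
  }
  vals
}

# Tm for index pairs (i, j) given precomputed features; vectorised over pairs.
predict_tm_indexed <- function(feat, i, j, model) {
  tab <- model$scores
  cs <- 0
  for (k in seq_len(ncol(feat$a))) {
    cs <- cs + score_sum(tab$core, unordered_key(feat$a[i, k], feat$a[j, k]),
                         tab$default_missing, "core")
  }
  es <- 0
  for (k in seq_len(ncol(feat$g))) {
    es <- es + score_sum(tab$electro, unordered_key(feat$g[i, k], feat$e[j, k]),
                         tab$default_missing, "electrostatic") +
               score_sum(tab$electro, unordered_key(feat$e[i, k], feat$g[j, k]),
                         tab$default_missing, "electrostatic")
  }
  hp <- (feat$hp_sum[i] + feat$hp_sum[j]) / (feat$hp_n[i] + feat$hp_n[j])
  model$w_hp * hp + model$w_cs * cs + model$w_es * es + model$intercept
}

#' Screen the full pairwise interactome of a peptide library
#'
#' Evaluates the predicted Tm of every unordered pair over the supplied
#' peptides, homodimers included: N peptides yield N(N+1)/2 evaluated pairs,
#' each computed exactly once (never bidirectionally). Interactions reaching
#' `criteria$min_desired_tm` are flagged as stored candidates for the
#' orthogonal-set searches; the full matrix remains available for export.
#' The screen is deterministic and its result is independent of peptide
#' input order (up to canonical pair ordering).
#'
#' @param peptides List of [registered_peptide()] objects with unique ids,
#'   normally the `retained` element of [import_filter()].
#' @param model A [tm_model()].
#' @param criteria A [screen_criteria()].
#' @return Object of class `interactome`: `peptides` (named list),
#'   `interactions` (data frame `idA`, `idB`, `tm`, `stored`, canonically
#'   ordered), and `provenance`.
#' @examples
#' oct <- heterospec_octet()
#' x <- screen_interactome(oct, default_tm_model(),
#'                         screen_criteria(max_homodimer_tm = Inf))
#' nrow(x$interactions)  # 36
#' @export
screen_interactome <- function(peptides, model = default_tm_model(),
                               criteria = screen_criteria()) {
  stopifnot(inherits(model, "tm_model"), inherits(criteria, "screen_criteria"))
  ids <- vapply(peptides, function(p) p$id, character(1L))
  if (anyDuplicated(ids)) {
    stop("peptide id collision: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(peptides) <- ids
  n <- length(peptides)
  if (n == 0L) {
    interactions <- data.frame(idA = character(), idB = character(),
                               tm = numeric(), stored = logical(),
                               stringsAsFactors = FALSE)
  } else {
    # unordered index pairs i <= j
    i <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
    j <- sequence(n - seq_len(n) + 1L) + i - 1L
    feat <- peptide_features(peptides, model)
    if (is.null(feat)) {
      tm <- mapply(function(a, b) predict_tm(peptides[[a]], peptides[[b]], model),
                   i, j)
    } else {
      tm <- predict_tm_indexed(feat, i, j, model)
    }
    idA <- ids[i]; idB <- ids[j]
    swap <- idA > idB
    tmpA <- idA; idA[swap] <- idB[swap]; idB[swap] <- tmpA[swap]
    interactions <- data.frame(idA = idA, idB = idB, tm = tm,
                               stored = tm >= criteria$min_desired_tm,
                               stringsAsFactors = FALSE)
    interactions <- interactions[order(interactions$idA, interactions$idB), ]
    rownames(interactions) <- NULL
  }
  structure(
    list(peptides = peptides, interactions = interactions,
         provenance = list(model = model$name, criteria = criteria,
                           n_peptides = n)),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", length(x$peptides), " peptides, ",
      nrow(x$interactions), " evaluated pairs (",
      sum(x$interactions$stored), " stored; model '",
      x$provenance$model, "')\n", sep = "")
  invisible(x)
}

#' Look up predicted Tm values in an interactome
#'
#' @param x An [screen_interactome()] result.
#' @param idA,idB Peptide id vectors (recycled); order is irrelevant.
#' @return Numeric vector of Tm values.
#' @export
tm_lookup <- function(x, idA, idB) {
  stopifnot(inherits(x, "interactome"))
  key <- ifelse(idA <= idB, paste0(idA, "\r", idB), paste0(idB, "\r", idA))
  tab <- stats::setNames(x$interactions$tm,
                         paste0(x$interactions$idA, "\r", x$interactions$idB))
  out <- tab[key]
  if (anyNA(out)) {
    stop("pair(s) absent from the interactome: ",
         paste(unique(paste0(idA, "-", idB)[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Export an interactome as heatmap matrix and long table
#'
#' Writes the symmetric N x N predicted-Tm matrix as TSV (row and column
#' labels are peptide ids; diagonal entries are homodimer predictions), and
#' optionally the canonical long-format table (`idA`, `idB`, `tm`,
#' `stored`). Output is deterministic, so identical interactomes produce
#' byte-identical files.
#'
#' @param x An [screen_interactome()] result.
#' @param matrix_path Path for the matrix TSV.
#' @param long_path Optional path for the long-format TSV.
#' @return Invisibly, the Tm matrix.
#' @export
export_heatmap <- function(x, matrix_path, long_path = NULL) {
  stopifnot(inherits(x, "interactome"))
  ids <- names(x$peptides)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- x$interactions
  m[cbind(ia$idA, ia$idB)] <- ia$tm
  m[cbind(ia$idB, ia$idA)] <- ia$tm
  fmt <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(id = rownames(m), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    ia_out <- ia
    ia_out$tm <- sprintf("%.17g", ia_out$tm)
    utils::write.table(ia_out, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(m)
}

#' Read back a heatmap matrix written by [export_heatmap()]
#'
#' @param matrix_path Path to the matrix TSV.
#' @return Numeric matrix with peptide-id dimnames.
#' @export
read_heatmap <- function(matrix_path) {
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
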