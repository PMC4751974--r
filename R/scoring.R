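#' Default core a-a' pairing free energies
#'
#' Free-energy scores (kcal/mol) for the core residue pairings used in the
#' Asn/Ile design space, derived from double-mutant thermodynamic analyses
#' of coiled-coil cores: Ile-Ile -9.2, Asn-Asn -2.4, Asn-Ile -0.5. The large
#' Asn-Ile penalty relative to the matched pairings is what lets two Asn and
#' two Ile per chain encode axial and partner specificity.
#'
#' @return Named numeric vector keyed by unordered residue pair.
#' @export
default_core_scores <- function() {
  c(II = -9.2, NN = -2.4, IN = -0.5)
}

#' Default electrostatic g-e' pairing free energies
#'
#' Free-energy scores (kcal/mol) for the flanking electrostatic contacts in
#' the Glu/Lys design space: Glu-Lys -1.2 (attractive), Glu-Glu +0.4 and
#' Lys-Lys -0.3 (both repulsive relative to Glu-Lys). Replacing one
#' attractive Glu-Lys contact with Glu-Glu costs +1.6 kcal/mol and with
#' Lys-Lys +0.9 kcal/mol.
#'
#' @return Named numeric vector keyed by unordered residue pair.
#' @export
default_electro_scores <- function() {
  c(EK = -1.2, EE = 0.4, KK = -0.3)
}

unordered_key <- function(resA, resB) {
  ifelse(resA <= resB, paste0(resA, resB), paste0(resB, resA))
}

#' Pairing free-energy table
#'
#' Bundles the core (a-a') and electrostatic (g-e' type) free-energy lookup
#' tables with a policy for residue pairs absent from them. Keys are
#' unordered residue pairs; `"EK"` and `"KE"` address the same entry.
#'
#' @param core,electro Named numeric vectors (kcal/mol) keyed by residue
#'   pair; defaults are [default_core_scores()] and
#'   [default_electro_scores()].
#' @param default_missing `"error"` (default; a missing pair usually means a
#'   register mistake) or `"zero"` (permissive mode for exploratory
#'   libraries whose residues extend beyond the tabulated pairs).
#' @return Object of class `pair_score_table`.
#' @export
pair_score_table <- function(core = default_core_scores(),
                             electro = default_electro_scores(),
                             default_missing = c("error", "zero")) {
  default_missing <- match.arg(default_missing)
  norm <- function(tab) {
    stopifnot(is.numeric(tab), !is.null(names(tab)),
              all(nchar(names(tab)) == 2L), all(is.finite(tab)))
    keys <- unordered_key(substr(names(tab), 1L, 1L), substr(names(tab), 2L, 2L))
    stats::setNames(as.numeric(tab), keys)
  }
  structure(
    list(core = norm(core), electro = norm(electro),
         default_missing = default_missing),
    class = "pair_score_table"
  )
}

lookup_pairs <- function(pairs, tab, what, policy) {
  if (nrow(pairs) == 0L) return(0)
  vals <- tab[unordered_key(pairs$resA, pairs$resB)]
  if (anyNA(vals)) {
    if (policy == "error") {
      missing <- unique(unordered_key(pairs$resA, pairs$resB)[is.na(vals)])
      stop("no ", what, " score for residue pair(s): ",
           paste(missing, collapse = ", "),
           " (set default_missing = \"zero\" to ignore)")
    }
    vals[is.na(vals)] <- 0
  }
  sum(vals)
}

#' Core free-energy sum of a parallel dimer
#'
#' Sums the pairing-table free energies over the enumerated a-a' core
#' contacts of the in-register parallel dimer. For any desired pair of the
#' shipped eight-peptide example (two Ile-Ile plus two Asn-Asn pairings)
#' this is -23.2 kcal/mol.
#'
#' @param pA,pB [registered_peptide()] objects.
#' @param table A [pair_score_table()].
#' @return Free energy in kcal/mol.
#' @examples
#' oct <- heterospec_octet()
#' delta_g_core(oct[["1"]], oct[["2"]])  # -23.2
#' delta_g_core(oct[["1"]], oct[["3"]])  # -2.0 (four Asn-Ile pairs)
#' @export
delta_g_core <- function(pA, pB, table = pair_score_table()) {
  stopifnot(inherits(table, "pair_score_table"))
  lookup_pairs(parallel_core_pairs(pA, pB), table$core, "core",
               table$default_missing)
}

#' Electrostatic free-energy sum of a dimer
#'
#' Sums the pairing-table free energies over the electrostatic contacts of
#' the chosen orientation: g-e' pairs for parallel dimers, g-g' and e-e'
#' pairs for antiparallel dimers.
#'
#' @inheritParams delta_g_core
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @return Free energy in kcal/mol.
#' @examples
#' oct <- heterospec_octet()
#' delta_g_electrostatic(oct[["1"]], oct[["2"]])  # -9.6 (8 x Glu-Lys)
#' @export
delta_g_electrostatic <- function(pA, pB, table = pair_score_table(),
                                  orientation = c("parallel", "antiparallel")) {
  stopifnot(inherits(table, "pair_score_table"))
  orientation <- match.arg(orientation)
  pairs <- switch(orientation,
                  parallel = parallel_electrostatic_pairs(pA, pB),
                  antiparallel = antiparallel_electrostatic_pairs(pA, pB))
  lookup_pairs(pairs, table$electro, "electrostatic", table$default_missing)
}

#' Default per-residue helical propensity table
#'
#' Helix propensities (kcal/mol, relative to Ala = 0; larger values are less
#' helix-favouring) following the Pace-Scholtz consensus scale. Used by the
#' Tm model as the "HP" term summarising how helix-competent the two chains
#' are before pairing energetics are considered.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
default_helicity_table <- function() {
  c(A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26,
    Q = 0.39, E = 0.40, I = 0.41, W = 0.49, S = 0.50,
    Y = 0.53, F = 0.54, H = 0.61, V = 0.61, N = 0.65,
    T = 0.66, C = 0.68, D = 0.69, G = 1.00, P = 3.16)
}

#' Mean helical propensity of a peptide pair
#'
#' Aggregates per-residue helical propensities as the mean over the non-cap
#' (scored) residues of both chains, which keeps the score independent of
#' chain length. Values are cached per peptide (keyed by sequence and
#' register) in `cache` when supplied, so interactome screens compute each
#' chain's contribution once.
#'
#' @inheritParams delta_g_core
#' @param table Named numeric propensity vector; default
#'   [default_helicity_table()].
#' @param cache Optional environment used to memoise per-peptide sums.
#' @return Mean propensity (same units as the table).
#' @export
helicity_score <- function(pA, pB, table = default_helicity_table(),
                           cache = NULL) {
  h <- single_chain_helicity(pA, table, cache)
  if (identical(pA$sequence, pB$sequence) &&
      identical(pA$register, pB$register)) {
    return(h$sum / h$n)
  }
  h2 <- single_chain_helicity(pB, table, cache)
  (h$sum + h2$sum) / (h$n + h2$n)
}

single_chain_helicity <- function(p, table, cache = NULL) {
  key <- paste0(p$sequence, "|", p$register)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- seq_chars(p)[reg_chars(p) != "-"]
  vals <- table[res]
  if (anyNA(vals)) {
    stop("residue(s) missing from the helicity table: ",
         paste(sort(unique(res[is.na(vals)])), collapse = ", "))
  }
  out <- list(sum = sum(vals), n = length(vals))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Linear predicted-Tm model for parallel dimeric coiled coils
#'
#' A bCIPA-style model: the predicted melting temperature of a parallel
#' dimeric coiled coil is a linear combination of the chains' mean helical
#' propensity (HP), the summed core pairing energies (CS) and the summed
#' electrostatic pairing energies (ES):
#' `Tm = w_hp * HP + w_cs * CS + w_es * ES + intercept`.
#'
#' The model is symmetric in its two peptide arguments. Coefficient sets are
#' pluggable and named; the shipped default, `"uncalibrated-demo"`, uses
#' round placeholder coefficients that order interactions correctly (any
#' negative `w_cs`/`w_es` ranks desired pairs above off-targets in this
#' design space) but is not a regression against measured melting data, so
#' absolute temperatures from it are demonstration values only.
#'
#' @param w_hp,w_cs,w_es,intercept Model coefficients (degrees C per unit of
#'   each term; intercept in degrees C).
#' @param helicity Per-residue propensity table.
#' @param scores A [pair_score_table()].
#' @param name Label for the coefficient set.
#' @return Object of class `tm_model` carrying an internal helicity cache.
#' @export
tm_model <- function(w_hp, w_cs, w_es, intercept,
                     helicity = default_helicity_table(),
                     scores = pair_score_table(),
                     name = "custom") {
  coefs <- c(w_hp = w_hp, w_cs = w_cs, w_es = w_es, intercept = intercept)
  if (anyNA(coefs) || !all(is.finite(coefs))) {
    stop("tm_model coefficients must all be finite numbers")
  }
  stopifnot(inherits(scores, "pair_score_table"))
  structure(
    list(w_hp = w_hp, w_cs = w_cs, w_es = w_es, intercept = intercept,
         helicity = helicity, scores = scores, name = name,
         cache = new.env(parent = emptyenv())),
    class = "tm_model"
  )
}

#' @rdname tm_model
#' @export
default_tm_model <- function() {
  tm_model(w_hp = -10, w_cs = -2, w_es = -4, intercept = 0,
           name = "uncalibrated-demo")
}

#' @export
print.tm_model <- function(x, ...) {
  cat("<tm_model> ", x$name, ": Tm = ", x$w_hp, "*HP + ", x$w_cs, "*CS + ",
      x$w_es, "*ES + ", x$intercept, "\n", sep = "")
  invisible(x)
}

#' Predict the melting temperature of a peptide pair
#'
#' Evaluates the linear Tm model on the parallel in-register dimer formed by
#' the two peptides (the model's fitted domain).
#'
#' @inheritParams delta_g_core
#' @param model A [tm_model()].
#' @return Predicted Tm in degrees C.
#' @examples
#' oct <- heterospec_octet()
#' m <- default_tm_model()
#' predict_tm(oct[["1"]], oct[["2"]], m)
#' @export
predict_tm <- function(pA, pB, model = default_tm_model()) {
  stopifnot(inherits(model, "tm_model"))
  hp <- helicity_score(pA, pB, model$helicity, cache = model$cache)
  cs <- delta_g_core(pA, pB, model$scores)
  es <- delta_g_electrostatic(pA, pB, model$scores, "parallel")
  model$w_hp * hp + model$w_cs * cs + model$w_es * es + model$intercept
}
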