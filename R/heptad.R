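AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# heptad letters in N->C order as used throughout: g a b c d e f, cycling
HEPTAD_CYCLE <- c("g", "a", "b", "c", "d", "e", "f")

heptad_next <- function(letter) {
  HEPTAD_CYCLE[match(letter, HEPTAD_CYCLE) %% 7L + 1L]
}

#' Registered coiled-coil peptide
#'
#' A peptide sequence annotated with its heptad register. Each residue is
#' assigned one of the seven heptad positions `g a b c d e f` (in the N-to-C
#' cyclic order `g -> a -> b -> c -> d -> e -> f -> g`), or `-` for capping
#' residues that are excluded from all interhelical scoring. In a parallel
#' dimeric coiled coil the `a` (and `d`) residues form the hydrophobic core
#' and the `g`/`e` residues form flanking electrostatic contacts.
#'
#' @param id Short unique label for the peptide.
#' @param sequence Amino-acid sequence, one-letter codes.
#' @param register String of the same length over `g a b c d e f -`;
#'   `-` marks cap residues.
#'
#' @return An object of class `registered_peptide` with fields `id`,
#'   `sequence` and `register`.
#'
#' @details Non-cap register positions must follow the cyclic heptad order
#'   without gaps. A warning is emitted if the peptide contains no complete
#'   `g..e` span (five residues apart), since no electrostatic pairs can then
#'   be enumerated.
#'
#' @examples
#' registered_peptide("p", "EIAALEK", "gabcdef")
#' @seealso [assign_register()] to derive the register from a start letter
#'   and cap lengths.
#' @export
registered_peptide <- function(id, sequence, register) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L,
            is.character(register), length(register) == 1L)
  sequence <- toupper(sequence)
  register <- tolower(register)
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  reg_chars <- strsplit(register, "", fixed = TRUE)[[1L]]
  if (length(seq_chars) != length(reg_chars)) {
    stop("register length (", length(reg_chars), ") does not match sequence length (",
         length(seq_chars), ") for peptide '", id, "'")
  }
  bad <- setdiff(seq_chars, AA_LETTERS)
  if (length(bad)) {
    stop("invalid residue(s) in peptide '", id, "': ",
         paste(sort(bad), collapse = ", "))
  }
  bad_reg <- setdiff(reg_chars, c(HEPTAD_CYCLE, "-"))
  if (length(bad_reg)) {
    stop("invalid register letter(s): ", paste(sort(bad_reg), collapse = ", "))
  }
  noncap <- reg_chars[reg_chars != "-"]
  if (length(noncap) > 1L) {
    expected <- vapply(noncap[-length(noncap)], heptad_next, character(1L))
    if (!all(noncap[-1L] == expected)) {
      stop("register of peptide '", id,
           "' does not follow the cyclic heptad order g,a,b,c,d,e,f")
    }
  }
  p <- structure(
    list(id = id, sequence = sequence, register = register),
    class = "registered_peptide"
  )
  if (nrow(ge_spans(p)) == 0L) {
    warning("peptide '", id, "' has no complete g..e span; ",
            "no electrostatic pairs can be enumerated")
  }
  p
}

#' @export
print.registered_peptide <- function(x, ...) {
  cat("<registered_peptide> ", x$id, "\n  ", x$sequence, "\n  ", x$register,
      "\n", sep = "")
  invisible(x)
}

#' Assign a heptad register to a sequence
#'
#' Annotates a peptide cyclically from a chosen start letter, marking optional
#' N- and C-terminal capping residues with `-` so they are excluded from
#' scoring. The library design used throughout this package registers chains
#' g-first and e-last so that every heptad contributes a full complement of
#' electrostatic contacts.
#'
#' @param sequence Amino-acid sequence (one-letter codes).
#' @param start_letter Heptad position of the first non-cap residue, one of
#'   `a`..`g`. Default `"g"`.
#' @param cap_prefix_len,cap_suffix_len Number of N-/C-terminal cap residues
#'   (annotated `-`).
#' @param id Peptide label; defaults to the sequence itself.
#'
#' @return A [registered_peptide()].
#' @examples
#' p <- assign_register("ASENAALEAKNAALKYKIAALKAEIAALEGAP",
#'                      cap_prefix_len = 2, cap_suffix_len = 3, id = "pep1")
#' residues_at(p, "a")
#' @export
assign_register <- function(sequence, start_letter = "g",
                            cap_prefix_len = 0L, cap_suffix_len = 0L,
                            id = sequence) {
  stopifnot(start_letter %in% HEPTAD_CYCLE,
            cap_prefix_len >= 0L, cap_suffix_len >= 0L)
  n <- nchar(sequence)
  n_core <- n - cap_prefix_len - cap_suffix_len
  if (n_core <= 0L) {
    stop("cap lengths (", cap_prefix_len, " + ", cap_suffix_len,
         ") leave no scored residues in a sequence of length ", n)
  }
  start <- match(start_letter, HEPTAD_CYCLE)
  core <- HEPTAD_CYCLE[(seq_len(n_core) + start - 2L) %% 7L + 1L]
  register <- paste0(strrep("-", cap_prefix_len),
                     paste(core, collapse = ""),
                     strrep("-", cap_suffix_len))
  registered_peptide(id, sequence, register)
}

seq_chars <- function(p) strsplit(p$sequence, "", fixed = TRUE)[[1L]]
reg_chars <- function(p) strsplit(p$register, "", fixed = TRUE)[[1L]]

#' Residues at a register position
#'
#' @param p A [registered_peptide()].
#' @param letter A heptad letter `a`..`g`.
#' @return Named character vector of residues at that register position, in
#'   N-to-C order; names are 1-based sequence positions.
#' @export
residues_at <- function(p, letter) {
  rc <- reg_chars(p)
  idx <- which(rc == letter)
  stats::setNames(seq_chars(p)[idx], idx)
}

# Complete g..e spans: positions i with register 'g' whose partner 'e' sits
# five residues C-terminal. With a contiguous register this enumerates the
# complete electrostatic heptads; a terminal heptad lacking its e residue
# contributes no span.
ge_spans <- function(p) {
  rc <- reg_chars(p)
  g <- which(rc == "g")
  g <- g[g + 5L <= length(rc)]
  g <- g[rc[g + 5L] == "e"]
  data.frame(g = g, e = g + 5L)
}

residue_pair_df <- function(kind = character(), posA = integer(),
                            posB = integer(), resA = character(),
                            resB = character()) {
  data.frame(kind = kind, posA = posA, posB = posB,
             resA = resA, resB = resB, stringsAsFactors = FALSE)
}

check_pair_args <- function(pA, pB) {
  stopifnot(inherits(pA, "registered_peptide"),
            inherits(pB, "registered_peptide"))
}

#' Core a-a' pairings of a parallel dimer
#'
#' Enumerates the interhelical core contacts of an in-register parallel
#' dimer: the n-th `a` residue of chain A packs against the n-th `a` residue
#' of chain B. No axial sliding is considered; alignment of Asn residues at
#' `a` positions stabilises a single axial register in this design space.
#'
#' @param pA,pB [registered_peptide()] objects.
#' @return A data frame with one row per pair: `kind` (`"core_aa"`), 1-based
#'   positions `posA`/`posB` and residues `resA`/`resB`.
#' @details If the chains have unequal numbers of `a` positions, pairing is
#'   truncated to the shorter chain (counted from the N terminus) with a
#'   warning. Zero `a` positions yield an empty data frame.
#' @examples
#' oct <- heterospec_octet()
#' parallel_core_pairs(oct[["1"]], oct[["2"]])  # 2x Asn-Asn + 2x Ile-Ile
#' @export
parallel_core_pairs <- function(pA, pB) {
  check_pair_args(pA, pB)
  aA <- residues_at(pA, "a")
  aB <- residues_at(pB, "a")
  n <- min(length(aA), length(aB))
  if (length(aA) != length(aB)) {
    warning("peptides '", pA$id, "' and '", pB$id,
            "' have unequal numbers of a positions; pairing truncated to ", n)
  }
  if (n == 0L) return(residue_pair_df())
  residue_pair_df(kind = rep("core_aa", n),
                  posA = as.integer(names(aA)[seq_len(n)]),
                  posB = as.integer(names(aB)[seq_len(n)]),
                  resA = unname(aA[seq_len(n)]),
                  resB = unname(aB[seq_len(n)]))
}

#' Electrostatic g-e' pairings of a parallel dimer
#'
#' For each complete electrostatic heptad n present in both chains, emits the
#' two salt-bridge contacts of the parallel in-register dimer: `g_n(A)` with
#' `e_n(B)` (the partner residue five positions C-terminal) and `e_n(A)` with
#' `g_n(B)`. For four complete heptads this yields the maximal eight
#' electrostatic contacts.
#'
#' @inheritParams parallel_core_pairs
#' @return Data frame of pairs with `kind` `"electro_ge"`/`"electro_eg"`.
#' @examples
#' oct <- heterospec_octet()
#' parallel_electrostatic_pairs(oct[["1"]], oct[["2"]])  # 8 Glu-Lys contacts
#' @export
parallel_electrostatic_pairs <- function(pA, pB) {
  check_pair_args(pA, pB)
  sA <- ge_spans(pA)
  sB <- ge_spans(pB)
  n <- min(nrow(sA), nrow(sB))
  if (nrow(sA) != nrow(sB)) {
    warning("peptides '", pA$id, "' and '", pB$id,
            "' have unequal numbers of complete g..e heptads; truncated to ", n)
  }
  if (n == 0L) return(residue_pair_df())
  scA <- seq_chars(pA); scB <- seq_chars(pB)
  i <- seq_len(n)
  rbind(
    residue_pair_df(kind = rep("electro_ge", n),
                    posA = sA$g[i], posB = sB$e[i],
                    resA = scA[sA$g[i]], resB = scB[sB$e[i]]),
    residue_pair_df(kind = rep("electro_eg", n),
                    posA = sA$e[i], posB = sB$g[i],
                    resA = scA[sA$e[i]], resB = scB[sB$g[i]])
  )
}

#' Electrostatic g-g' and e-e' pairings of an antiparallel dimer
#'
#' In the antiparallel orientation the chains run in opposite directions, so
#' with N complete electrostatic heptads the n-th heptad of chain A faces the
#' (N+1-n)-th heptad of chain B, and the contacts are `g_n(A)-g_(N+1-n)(B)`
#' and `e_n(A)-e_(N+1-n)(B)`. Homodimers whose antiparallel contacts are all
#' attractive (Glu-Lys) can gain unplanned stability; see
#' [antiparallel_complementary()] and the `antiparallel_filter` screening
#' option.
#'
#' @inheritParams parallel_core_pairs
#' @return Data frame of pairs with `kind` `"electro_gg"`/`"electro_ee"`.
#' @export
antiparallel_electrostatic_pairs <- function(pA, pB) {
  check_pair_args(pA, pB)
  sA <- ge_spans(pA)
  sB <- ge_spans(pB)
  n <- min(nrow(sA), nrow(sB))
  if (nrow(sA) != nrow(sB)) {
    warning("peptides '", pA$id, "' and '", pB$id,
            "' have unequal numbers of complete g..e heptads; truncated to ", n)
  }
  if (n == 0L) return(residue_pair_df())
  scA <- seq_chars(pA); scB <- seq_chars(pB)
  i <- seq_len(n)
  j <- rev(i)
  rbind(
    residue_pair_df(kind = rep("electro_gg", n),
                    posA = sA$g[i], posB = sB$g[j],
                    resA = scA[sA$g[i]], resB = scB[sB$g[j]]),
    residue_pair_df(kind = rep("electro_ee", n),
                    posA = sA$e[i], posB = sB$e[j],
                    resA = scA[sA$e[i]], resB = scB[sB$e[j]])
  )
}

#' Core a-d' pairings of an antiparallel dimer
#'
#' Buried polar contacts in antiparallel dimers occur between `a` and `d'`
#' positions. These pairs are enumerable for inspection but excluded from
#' scoring by default: with Leu fixed at every `d` position they carry no
#' specificity signal in this design space.
#'
#' @inheritParams parallel_core_pairs
#' @return Data frame of pairs with `kind` `"core_ad"`.
#' @export
antiparallel_core_pairs <- function(pA, pB) {
  check_pair_args(pA, pB)
  aA <- residues_at(pA, "a")
  dB <- residues_at(pB, "d")
  n <- min(length(aA), length(dB))
  if (n == 0L) return(residue_pair_df())
  i <- seq_len(n)
  j <- rev(i)
  residue_pair_df(kind = rep("core_ad", n),
                  posA = as.integer(names(aA)[i]),
                  posB = as.integer(names(dB)[j]),
                  resA = unname(aA[i]), resB = unname(dB[j]))
}

#' Is a homodimer fully electrostatically complementary when antiparallel?
#'
#' Tests whether every antiparallel electrostatic contact of the peptide with
#' itself is an attractive Glu-Lys/Lys-Glu pairing. Such sequences can form
#' unplanned stable antiparallel homodimers and are removed at import when
#' the antiparallel screening filter is enabled.
#'
#' @param p A [registered_peptide()].
#' @return `TRUE` if the peptide has at least one antiparallel electrostatic
#'   contact and all of them are E-K or K-E.
#' @examples
#' oct <- heterospec_octet()
#' antiparallel_complementary(oct[["5"]])  # TRUE
#' antiparallel_complementary(oct[["1"]])  # FALSE
#' @export
antiparallel_complementary <- function(p) {
  pairs <- antiparallel_electrostatic_pairs(p, p)
  nrow(pairs) > 0L &&
    all(paste0(pairs$resA, pairs$resB) %in% c("EK", "KE"))
}
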