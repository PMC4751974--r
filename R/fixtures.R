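#' The worked-example library template
#'
#' The 27-position degenerate template behind the shipped example library:
#' four heptads registered g-first and ending at `e`, Leu fixed at every `d`
#' position, `h` = Asn/Ile options at the four core `a` positions and `p` =
#' Glu/Lys options at all eight electrostatic `e`/`g` positions (4096
#' members; 1536 after the two-Asn/two-Ile core constraint). Members carry
#' an N-terminal `AS` cap and a C-terminal `GAP` cap, excluded from scoring.
#'
#' @return List with fields `text`, `symbols`, `start_letter`, `cap_prefix`,
#'   `cap_suffix` and `constraint` (the two-Asn/two-Ile core constraint in
#'   [parse_constraint()] form).
#' @examples
#' tpl <- heterospec_template()
#' parse_template(tpl$text, tpl$symbols)$size  # 4096
#' @export
heterospec_template <- function() {
  list(
    text = "phAALpAphAALpYphAALpAphAALp",
    symbols = list(h = c("N", "I"), p = c("E", "K")),
    start_letter = "g",
    cap_prefix = "AS",
    cap_suffix = "GAP",
    constraint = "a:N=2,I=2"
  )
}

OCTET_SEQUENCES <- c(
  "1" = "ASENAALEAKNAALKYKIAALKAEIAALEGAP",
  "2" = "ASKNAALKAENAALEYEIAALEAKIAALKGAP",
  "3" = "ASEIAALEAEIAALEYENAALEAENAALEGAP",
  "4" = "ASKIAALKAKIAALKYKNAALKAKNAALKGAP",
  "5" = "ASKNAALKAEIAALEYKIAALKAENAALEGAP",
  "6" = "ASENAALEAKIAALKYEIAALEAKNAALKGAP",
  "7" = "ASKIAALKAKNAALKYENAALEAEIAALEGAP",
  "8" = "ASEIAALEAENAALEYKNAALKAKIAALKGAP"
)

#' The eight-peptide worked example
#'
#' The eight 32-residue peptides of the selected heterospecific quadruple
#' (desired heterodimers 1-2, 3-4, 5-6 and 7-8), each a member of the
#' [heterospec_template()] library: `AS` cap, 27-residue g-registered core,
#' `GAP` cap. Their 36-pair mini-interactome exercises every interaction
#' class the screen distinguishes (4 desired pairs, 8 homodimers, 8
#' intrapair and 16 interpair heterodimeric off-targets).
#'
#' @return Named list of eight [registered_peptide()] objects with ids
#'   `"1"`..`"8"`.
#' @examples
#' oct <- heterospec_octet()
#' oct[["4"]]$sequence
#' @export
heterospec_octet <- function() {
  out <- lapply(names(OCTET_SEQUENCES), function(id) {
    assign_register(OCTET_SEQUENCES[[id]], start_letter = "g",
                    cap_prefix_len = 2L, cap_suffix_len = 3L, id = id)
  })
  stats::setNames(out, names(OCTET_SEQUENCES))
}

#' The desired heterodimers of the worked example
#'
#' @return Two-column character matrix of the four designated desired pairs.
#' @export
heterospec_desired_pairs <- function() {
  cbind(idA = c("1", "3", "5", "7"), idB = c("2", "4", "6", "8"))
}
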