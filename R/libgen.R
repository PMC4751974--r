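#' Parse a degenerate library template
#'
#' A template describes a combinatorial peptide library one position at a
#' time. In protein mode each character is either a fixed residue or a
#' wildcard symbol resolved through `symbol_table` to a set of allowed
#' residues (e.g. `h` = Asn/Ile at core `a` positions, `p` = Glu/Lys at
#' electrostatic `e`/`g` positions). In DNA mode the template is a string of
#' IUPAC (possibly degenerate) nucleotide codes whose length is a multiple
#' of three; see [expand_degenerate_dna()].
#'
#' @param text Template string. Whitespace is ignored.
#' @param symbol_table Named list mapping each wildcard symbol to a character
#'   vector of allowed residues (protein mode). Characters not in the table
#'   must be valid one-letter residue codes and are treated as fixed.
#' @param mode `"protein"` or `"dna"`.
#'
#' @return An object of class `library_template` with fields `positions` (a
#'   list of sorted residue-option vectors, protein mode), `mode`, and
#'   `size` (the Cartesian-product size).
#' @examples
#' tpl <- parse_template("phAALpA", symbol_table = list(h = c("N", "I"),
#'                                                      p = c("E", "K")))
#' tpl$size  # 2 * 2 * 2 = 8
#' @export
parse_template <- function(text, symbol_table = list(), mode = c("protein", "dna")) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty template")
  if (mode == "dna") {
    if (length(chars) %% 3L != 0L) {
      stop("DNA-mode template length must be divisible by 3")
    }
    chars <- toupper(chars)
    bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad)) {
      stop("non-IUPAC nucleotide code(s) in template: ",
           paste(sort(unique(bad)), collapse = ", "))
    }
    positions <- lapply(chars, function(ch) {
      sort(strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "", fixed = TRUE)[[1L]])
    })
  } else {
    if (length(symbol_table)) {
      stopifnot(!is.null(names(symbol_table)), all(nzchar(names(symbol_table))))
      for (sym in names(symbol_table)) {
        opts <- symbol_table[[sym]]
        bad <- setdiff(opts, AA_LETTERS)
        if (length(bad) || length(opts) < 2L) {
          stop("symbol '", sym, "' must map to >= 2 valid residues")
        }
      }
    }
    positions <- lapply(chars, function(ch) {
      if (ch %in% names(symbol_table)) {
        sort(unique(symbol_table[[ch]]))
      } else if (toupper(ch) %in% AA_LETTERS) {
        toupper(ch)
      } else {
        stop("unknown template symbol '", ch,
             "': not a residue and absent from the symbol table")
      }
    })
  }
  structure(
    list(positions = positions, mode = mode,
         size = prod(vapply(positions, length, numeric(1L)))),
    class = "library_template"
  )
}

#' @export
print.library_template <- function(x, ...) {
  n_var <- sum(vapply(x$positions, length, integer(1L)) > 1L)
  cat("<library_template> mode=", x$mode, ", ", length(x$positions),
      " positions (", n_var, " variable), ", format(x$size, big.mark = ","),
      " members\n", sep = "")
  invisible(x)
}

#' Exact residue-count constraint at one register position class
#'
#' Restricts library members to those carrying exact residue counts at the
#' positions of one register class, e.g. exactly two Asn and two Ile at the
#' four core `a` positions — the constraint that guarantees every undesired
#' in-register heterodimer acquires destabilising Asn-Ile core pairs.
#'
#' @param register_letter Heptad letter the constraint applies to.
#' @param residue_counts Named integer vector of exact required counts; the
#'   counts must sum to the number of template positions of that class.
#' @return An object of class `composition_constraint`.
#' @examples
#' composition_constraint("a", c(N = 2, I = 2))
#' parse_constraint("a:N=2,I=2")
#' @export
composition_constraint <- function(register_letter, residue_counts) {
  stopifnot(register_letter %in% HEPTAD_CYCLE,
            is.numeric(residue_counts), length(residue_counts) >= 1L,
            !is.null(names(residue_counts)), all(nzchar(names(residue_counts))),
            all(residue_counts >= 0))
  structure(
    list(register_letter = register_letter,
         residue_counts = residue_counts),
    class = "composition_constraint"
  )
}

#' @rdname composition_constraint
#' @param text Constraint in the compact form `"a:N=2,I=2"`.
#' @export
parse_constraint <- function(text) {
  m <- regmatches(text, regexec("^([a-g]):(.+)$", text))[[1L]]
  if (length(m) != 3L) stop("cannot parse constraint '", text, "'")
  parts <- strsplit(m[[3L]], ",", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("cannot parse constraint '", text, "'")
  counts <- as.integer(vapply(kv, `[`, character(1L), 2L))
  names(counts) <- vapply(kv, `[`, character(1L), 1L)
  composition_constraint(m[[2L]], counts)
}

satisfies_constraint <- function(p, constraint) {
  res <- residues_at(p, constraint$register_letter)
  counts <- constraint$residue_counts
  all(vapply(names(counts),
             function(r) sum(res == r) == counts[[r]], logical(1L)))
}

# Enumerate template members in lexicographic order without materialising
# the whole Cartesian product: `fun` is called on successive chunks of
# sequences (character vectors), keeping memory bounded for large templates.
template_apply <- function(template, fun, chunk_size = 65536L) {
  opts <- template$positions
  n_opts <- vapply(opts, length, numeric(1L))
  total <- prod(n_opts)
  if (total == 0) return(invisible(NULL))
  # mixed-radix digits; leftmost position is the most significant so that
  # sorted per-position options give lexicographic output order
  weights <- rev(cumprod(rev(c(n_opts[-1L], 1))))
  done <- 0
  while (done < total) {
    idx <- done + seq_len(min(chunk_size, total - done)) - 1
    mat <- vapply(seq_along(opts), function(j) {
      opts[[j]][(idx %/% weights[j]) %% n_opts[j] + 1]
    }, character(length(idx)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    fun(apply(mat, 1L, paste, collapse = ""))
    done <- done + length(idx)
  }
  invisible(NULL)
}

#' Expand a protein-level template into an explicit peptide library
#'
#' Enumerates every member of the Cartesian product over the template's
#' per-position residue options, in deterministic lexicographic order, and
#' optionally filters members through composition constraints. Each retained
#' member is returned as a [registered_peptide()] with the register assigned
#' from `start_letter`, after attaching optional fixed capping sequences
#' (annotated `-`, excluded from scoring).
#'
#' @param template A [parse_template()] result in protein mode.
#' @param constraints A [composition_constraint()], a list of them, or `NULL`.
#' @param start_letter Heptad position of the first template residue
#'   (default `"g"`, the register convention that maximises electrostatic
#'   contacts for a template ending at `e`).
#' @param cap_prefix,cap_suffix Fixed capping sequences added around the
#'   template-encoded core (default none).
#' @param id_prefix Member ids are `id_prefix` followed by the 1-based index
#'   within the retained, lexicographically ordered library, so ids are
#'   stable across runs.
#'
#' @return List of [registered_peptide()] objects, lexicographically ordered
#'   by core sequence, duplicate-free.
#' @examples
#' tpl <- parse_template("phAALpAphAALpYphAALpAphAALp",
#'                       symbol_table = list(h = c("N", "I"), p = c("E", "K")))
#' tpl$size  # 4096
#' lib <- expand_template(tpl, constraints = parse_constraint("a:N=2,I=2"))
#' length(lib)  # 1536
#' @export
expand_template <- function(template, constraints = NULL, start_letter = "g",
                            cap_prefix = "", cap_suffix = "",
                            id_prefix = "lib") {
  stopifnot(inherits(template, "library_template"))
  if (template$mode != "protein") {
    stop("expand_template() requires a protein-mode template; ",
         "use expand_degenerate_dna() for DNA mode")
  }
  if (inherits(constraints, "composition_constraint")) {
    constraints <- list(constraints)
  }
  register <- suppressWarnings(assign_register(
    strrep("A", nchar(cap_prefix) + length(template$positions) + nchar(cap_suffix)),
    start_letter = start_letter,
    cap_prefix_len = nchar(cap_prefix),
    cap_suffix_len = nchar(cap_suffix)
  ))$register
  cores <- character(0L)
  template_apply(template, function(chunk) {
    cores <<- c(cores, chunk)
  })
  cores <- unique(cores)
  seqs <- paste0(cap_prefix, cores, cap_suffix)
  keep <- rep(TRUE, length(seqs))
  if (!is.null(constraints) && length(seqs)) {
    # constraints act on register classes; evaluate on a prototype register
    rc <- strsplit(register, "", fixed = TRUE)[[1L]]
    for (con in constraints) {
      idx <- which(rc == con$register_letter)
      counts <- con$residue_counts
      if (sum(counts) != length(idx)) {
        stop("constraint counts for register '", con$register_letter,
             "' sum to ", sum(counts), " but the template has ", length(idx),
             " such positions")
      }
      resmat <- do.call(rbind, strsplit(substring(seqs, 1L, max(idx)), "",
                                        fixed = TRUE))[, idx, drop = FALSE]
      for (r in names(counts)) {
        keep <- keep & rowSums(resmat == r) == counts[[r]]
      }
    }
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0L) {
    warning("no library members satisfy the constraints; empty library")
    return(list())
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- registered_peptide(paste0(id_prefix, i), seqs[[i]], register)
  }
  out
}

#' Expand a degenerate-codon DNA template to the protein level
#'
#' Enumerates every concrete codon assignment of a DNA-mode template (IUPAC
#' degenerate codes), translates with the standard genetic code, and
#' deduplicates at the protein level (synonymous codons collapse: a library
#' is a set of peptides). DNA variants containing stop codons are flagged
#' and excluded from the peptide list.
#'
#' @param template A [parse_template()] result in DNA mode.
#' @return List with elements `peptides` (sorted unique character vector),
#'   `n_dna_variants` (total concrete DNA sequences) and `n_stop_variants`
#'   (variants discarded for containing a stop codon).
#' @examples
#' expand_degenerate_dna(parse_template("RAW", mode = "dna"))$peptides
#' # "D" "E" "K" "N"
#' @export
expand_degenerate_dna <- function(template) {
  stopifnot(inherits(template, "library_template"))
  if (template$mode != "dna") stop("template is not in DNA mode")
  dna <- character(0L)
  template_apply(template, function(chunk) dna <<- c(dna, chunk))
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna), no.init.codon = TRUE
  ))
  has_stop <- grepl("*", prot, fixed = TRUE)
  list(peptides = sort(unique(prot[!has_stop])),
       n_dna_variants = length(dna),
       n_stop_variants = sum(has_stop))
}
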