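#' Read peptides with heptad registers from FASTA
#'
#' Reads a protein FASTA file whose headers optionally carry the register as
#' a `register=` key (e.g. `>pep1 register=--gabcdef...---`). Registers may
#' instead be supplied through a plain-text sidecar file with two
#' whitespace-separated columns, id and register; the sidecar wins when both
#' are present. Peptides with no register from either source are registered
#' with [assign_register()] defaults (g-start, no caps).
#'
#' @param path FASTA file path.
#' @param sidecar Optional sidecar file path.
#' @return List of [registered_peptide()] objects (empty for an empty file).
#' @export
read_fasta_with_register <- function(path, sidecar = NULL) {
  if (file.exists(path) && file.size(path) == 0) return(list())
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) return(list())
  headers <- names(seqs)
  ids <- sub("[[:space:]].*$", "", headers)
  regs <- rep(NA_character_, length(seqs))
  m <- regmatches(headers, regexpr("register=[^[:space:]]+", headers))
  has_tag <- grepl("register=", headers)
  regs[has_tag] <- sub("^register=", "", m)
  if (!is.null(sidecar)) {
    sc <- utils::read.table(sidecar, header = FALSE,
                            col.names = c("id", "register"),
                            colClasses = "character")
    hit <- match(ids, sc$id)
    regs[!is.na(hit)] <- sc$register[hit[!is.na(hit)]]
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    out[[i]] <- if (is.na(regs[i])) {
      assign_register(s, id = ids[i])
    } else {
      registered_peptide(ids[i], s, regs[i])
    }
  }
  out
}

#' Write peptides with registers to FASTA
#'
#' Writes headers of the form `>id register=...` so that
#' [read_fasta_with_register()] round-trips the register annotation.
#'
#' @param peptides List of [registered_peptide()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_with_register <- function(peptides, path) {
  lines <- unlist(lapply(peptides, function(p) {
    c(paste0(">", p$id, " register=", p$register), p$sequence)
  }))
  if (is.null(lines)) lines <- character(0L)
  writeLines(lines, path)
  invisible(path)
}

criteria_from_config <- function(cfg) {
  args <- cfg[intersect(names(cfg), names(formals(screen_criteria)))]
  do.call(screen_criteria, args)
}

model_from_config <- function(cfg) {
  if (is.null(cfg)) return(default_tm_model())
  tab <- pair_score_table(
    core = if (is.null(cfg$score_tables$core)) default_core_scores()
           else unlist(cfg$score_tables$core),
    electro = if (is.null(cfg$score_tables$electro)) default_electro_scores()
              else unlist(cfg$score_tables$electro),
    default_missing = if (is.null(cfg$score_tables$default_missing)) "error"
                      else cfg$score_tables$default_missing
  )
  hel <- if (is.null(cfg$helicity)) default_helicity_table()
         else unlist(cfg$helicity)
  co <- cfg$tm_model$coefficients
  if (is.null(co)) {
    m <- default_tm_model()
    co <- list(w_hp = m$w_hp, w_cs = m$w_cs, w_es = m$w_es,
               intercept = m$intercept)
  }
  tm_model(w_hp = co$w_hp, w_cs = co$w_cs, w_es = co$w_es,
           intercept = co$intercept, helicity = hel, scores = tab,
           name = if (is.null(cfg$tm_model$name)) "config" else cfg$tm_model$name)
}

#' Read a run configuration
#'
#' Loads a YAML configuration with sections `template` (text, symbols,
#' start_letter, caps, constraint), `score_tables`, `helicity`, `tm_model`
#' (`coefficients`: w_hp, w_cs, w_es, intercept), `criteria` (the
#' [screen_criteria()] fields) and `output` (paths). Any omitted section
#' falls back to the package defaults.
#'
#' @param path YAML file path.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", class(cfg)))
}

#' Write the worked-example fixture files
#'
#' Writes a self-contained, byte-reproducible set of input files for the
#' shipped example: the degenerate template and its symbol table, the eight
#' selected peptides as register-annotated FASTA, and a full YAML run
#' configuration carrying the default score tables, helicity table, Tm-model
#' coefficients and screening criteria (homodimer cutoff 10, desired
#' minimum 70, pair off-target ceiling 20 with separation 50, quadruple
#' ceiling 30 with separation 40).
#'
#' @param outdir Output directory (created if needed).
#' @return Invisibly, named character vector of the written paths.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tpl <- heterospec_template()
  paths <- c(
    template = file.path(outdir, "template.txt"),
    symbols = file.path(outdir, "symbols.yaml"),
    octet = file.path(outdir, "octet.fasta"),
    config = file.path(outdir, "config.yaml")
  )
  writeLines(tpl$text, paths[["template"]])
  yaml::write_yaml(tpl$symbols, paths[["symbols"]])
  write_fasta_with_register(heterospec_octet(), paths[["octet"]])
  m <- default_tm_model()
  cfg <- list(
    template = list(text = tpl$text, symbols = tpl$symbols,
                    start_letter = tpl$start_letter,
                    cap_prefix = tpl$cap_prefix, cap_suffix = tpl$cap_suffix,
                    constraint = tpl$constraint),
    score_tables = list(core = as.list(default_core_scores()),
                        electro = as.list(default_electro_scores()),
                        default_missing = "error"),
    helicity = as.list(default_helicity_table()),
    tm_model = list(name = m$name,
                    coefficients = list(w_hp = m$w_hp, w_cs = m$w_cs,
                                        w_es = m$w_es, intercept = m$intercept)),
    criteria = list(max_homodimer_tm = 10, min_desired_tm = 70,
                    max_offtarget_tm_pairs = 20, min_delta_tm_pairs = 50,
                    max_offtarget_tm_quads = 30, min_delta_tm_quads = 40,
                    antiparallel_filter = FALSE)
  )
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Run the full design pipeline
#'
#' Executes the four stages in order: (1) generate the library (expand the
#' configured template, or read `library_fasta`), (2) import-filter and
#' screen the full pairwise interactome, (3) search the stored interactions
#' for orthogonal 4-peptide sets, (4) combine those into orthogonal
#' 8-peptide sets. Artifacts (library FASTA, long interaction table,
#' heatmap matrix, set tables) are written to `outdir` when given; stage
#' counts are returned and logged.
#'
#' @param config A list or `run_config` (see [read_run_config()]), or a
#'   path to a YAML file.
#' @param outdir Optional output directory for artifacts.
#' @param quiet Suppress stage logging.
#' @return List of class `pipeline_report`: stage counts
#'   (`library_size`, `n_rejected_homodimer`, `n_rejected_antiparallel`,
#'   `n_retained`, `evaluated_pairs`, `stored_interactions`, `pair_sets`,
#'   `quadruple_sets`) plus the `interactome`, `pairs` and `quadruples`
#'   objects.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  model <- stage("configure", model_from_config(config))
  criteria <- stage("configure", if (is.null(config$criteria)) {
    screen_criteria()
  } else {
    criteria_from_config(config$criteria)
  })

  library_peptides <- stage("generate-library", {
    if (!is.null(config$library_fasta)) {
      read_fasta_with_register(config$library_fasta,
                               sidecar = config$library_sidecar)
    } else if (!is.null(config$template)) {
      tc <- config$template
      tpl <- parse_template(tc$text, tc$symbols)
      cons <- if (is.null(tc$constraint)) NULL else parse_constraint(tc$constraint)
      expand_template(tpl, constraints = cons,
                      start_letter = if (is.null(tc$start_letter)) "g" else tc$start_letter,
                      cap_prefix = if (is.null(tc$cap_prefix)) "" else tc$cap_prefix,
                      cap_suffix = if (is.null(tc$cap_suffix)) "" else tc$cap_suffix)
    } else {
      list()
    }
  })
  say("generate-library: ", length(library_peptides), " peptides")

  filt <- stage("import-filter", import_filter(library_peptides, model, criteria))
  n_homo <- sum(filt$rejected$reason == "homodimer_tm")
  n_ap <- sum(filt$rejected$reason == "antiparallel_complementary")
  say("import-filter: ", length(filt$retained), " retained (",
      n_homo, " homodimer, ", n_ap, " antiparallel rejections)")

  x <- stage("screen", screen_interactome(filt$retained, model, criteria))
  say("screen: ", nrow(x$interactions), " evaluated pairs, ",
      sum(x$interactions$stored), " stored")

  pairs <- stage("find-pairs", find_pairs(x, criteria))
  say("find-pairs: ", length(pairs), " orthogonal 4-peptide sets")

  quads <- stage("find-quadruples", find_quadruples(pairs, x, criteria))
  say("find-quadruples: ", length(quads), " orthogonal 8-peptide sets")

  if (!is.null(outdir)) {
    stage("write-artifacts", {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta_with_register(library_peptides,
                                file.path(outdir, "library.fasta"))
      utils::write.table(filt$rejected, file.path(outdir, "rejections.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(filt$retained) <= 2048L && length(filt$retained) > 0L) {
        export_heatmap(x, file.path(outdir, "heatmap.tsv"),
                       file.path(outdir, "interactions.tsv"))
      } else if (length(filt$retained) > 0L) {
        ia <- x$interactions
        utils::write.table(ia[ia$stored, , drop = FALSE],
                           file.path(outdir, "interactions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      utils::write.table(sets_table(pairs), file.path(outdir, "pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sets_table(quads), file.path(outdir, "quadruples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  structure(
    list(library_size = length(library_peptides),
         n_rejected_homodimer = n_homo,
         n_rejected_antiparallel = n_ap,
         n_retained = length(filt$retained),
         evaluated_pairs = nrow(x$interactions),
         stored_interactions = sum(x$interactions$stored),
         pair_sets = length(pairs),
         quadruple_sets = length(quads),
         interactome = x, pairs = pairs, quadruples = quads),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n",
      "  library_size:        ", x$library_size, "\n",
      "  rejected homodimer:  ", x$n_rejected_homodimer, "\n",
      "  rejected antiparall: ", x$n_rejected_antiparallel, "\n",
      "  retained:            ", x$n_retained, "\n",
      "  evaluated_pairs:     ", x$evaluated_pairs, "\n",
      "  stored_interactions: ", x$stored_interactions, "\n",
      "  pair_sets:           ", x$pair_sets, "\n",
      "  quadruple_sets:      ", x$quadruple_sets, "\n", sep = "")
  invisible(x)
}
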