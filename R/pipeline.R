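# End-to-end orchestration: ASR (or a precomputed state table) -> panel
# variable-site detection -> combination enumeration -> physicochemical
# recoding -> extant comparison -> report bundle, plus the multi-model
# sensitivity comparison.

read_id_file <- function(x) {
  if (length(x) == 1L && is.character(x) && file.exists(x))
    return(scan(x, what = character(), quiet = TRUE, comment.char = "#"))
  as.character(x)
}

resolve_input <- function(x, reader, class_) {
  if (is.null(x)) return(NULL)
  if (inherits(x, class_)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("file not found: ", x)
    return(reader(x))
  }
  stop("expected a ", class_, " object or a file path")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order and writes every stage output plus
#' `summary.json` and the resolved configuration to `outdir`. Either a raw
#' alignment + tree (the engine runs) or a precomputed state table may be
#' supplied; downstream stages are identical in both cases. Any stage
#' error aborts with the stage name; outputs of completed stages are kept.
#'
#' @param config A list or path to a YAML file with fields: `alignment`,
#'   `tree`, `outgroup`, `ingroup` (paths/objects/id vectors);
#'   `state_table` (optional precomputed posteriors; skips the engine);
#'   `models` (list of `list(name, categories)` blocks, default LG with
#'   4-category gamma, shape 1); `panel` (default the packaged 24-site
#'   panel); `clades` (optional id -> clade file or named vector);
#'   `threshold` (default 0.10); `rare_max` (default 2); `outdir`; `seed`
#'   (recorded in provenance).
#' @return Invisibly, a list with `state_tables` (per model), `variable`,
#'   `combos`, `classification`, `co_occurrence`, `sensitivity` (when > 1
#'   model) and `summary`. When no panel site is variable at the threshold
#'   (a fully conserved ancestor), the combination stages are skipped with
#'   a message and `combos`/`classification` are `NULL`.
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(threshold = 0.10, rare_max = 2L,
                                outdir = tempfile("ancsr_run_")),
                           config)
  if (!(is.numeric(cfg$threshold) && cfg$threshold > 0 && cfg$threshold < 1))
    stop("threshold must be in (0, 1)")
  if (cfg$rare_max < 1L) stop("rare_max must be >= 1")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  aln <- stage("load_alignment",
               resolve_input(cfg$alignment, read_fasta, "protein_alignment"))
  panel <- stage("load_panel", {
    p <- resolve_input(cfg$panel, read_panel, "site_panel")
    if (is.null(p)) nif_panel() else p
  })
  clades <- stage("load_clades", {
    if (is.null(cfg$clades)) NULL
    else if (is.character(cfg$clades) && length(cfg$clades) == 1L &&
             file.exists(cfg$clades)) {
      df <- utils::read.table(cfg$clades, header = FALSE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
      stats::setNames(df[[2]], df[[1]])
    } else cfg$clades
  })

  model_blocks <- cfg$models
  if (is.null(model_blocks))
    model_blocks <- list(list(name = "LG", categories = list(alpha = 1, k = 4)))
  if (!is.null(model_blocks$name)) model_blocks <- list(model_blocks)

  state_tables <- stage("asr", {
    if (!is.null(cfg$state_table)) {
      st <- resolve_input(cfg$state_table, read_state_table, "state_table")
      list(precomputed = st)
    } else {
      if (is.null(aln)) stop("need an alignment (or a state_table)")
      tree <- resolve_input(cfg$tree, read_newick, "phylo")
      if (is.null(tree)) stop("need a tree (or a state_table)")
      outgroup <- read_id_file(cfg$outgroup)
      ingroup <- read_id_file(cfg$ingroup)
      sts <- lapply(model_blocks, function(b) {
        cats <- b$categories
        if (is.list(cats) && !is.data.frame(cats) &&
            all(c("weight", "rate") %in% names(cats)))
          cats <- data.frame(weight = unlist(cats$weight),
                             rate = unlist(cats$rate))
        model <- load_model(b$name, categories = if (is.null(cats)) "uniform" else cats)
        run_asr_pipeline(aln, tree, model, outgroup, ingroup, quiet = TRUE)
      })
      names(sts) <- vapply(model_blocks, function(b) b$name, character(1))
      sts
    }
  })
  for (nm in names(state_tables))
    write_state_table(state_tables[[nm]],
                      file.path(cfg$outdir, paste0("ancestor_", nm, ".state")))

  primary <- state_tables[[1]]
  vs <- stage("variable_sites",
              detect_variable_sites(primary, panel, threshold = cfg$threshold))
  utils::write.table(as.data.frame(vs),
                     file.path(cfg$outdir, "variable_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  combos <- NULL
  if (any(vs$variable)) {
    combos <- stage("combinations", enumerate_combinations(vs))
    write_combinations(combos, file.path(cfg$outdir, "combinations.tsv"))
  } else {
    message("no panel site is variable at P > ", cfg$threshold,
            "; skipping combination stages")
  }

  scheme <- physchem_scheme()
  cls <- NULL
  coocc <- NULL
  if (!is.null(combos) && !is.null(aln) && !is.null(cfg$ingroup)) {
    ingroup <- read_id_file(cfg$ingroup)
    profile <- stage("extant_profiles",
                     extract_profiles(aln, attr(combos, "columns"), ingroup,
                                      clade_map = clades, scheme = scheme))
    writeLines(c("# sequences excluded from extant counts (gap/X at a panel column)",
                 profile$excluded),
               file.path(cfg$outdir, "exclusions.tsv"))
    cls <- stage("classify",
                 classify(combos, profile, scheme = scheme,
                          rare_max = cfg$rare_max))
    utils::write.table(cls$table,
                       file.path(cfg$outdir, "combos_classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(attr(combos, "columns")) >= 2L) {
      coocc <- stage("co_occurrence", co_occurrence_report(profile, combos))
      utils::write.table(coocc, file.path(cfg$outdir, "co_occurrence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  sens <- NULL
  if (length(state_tables) > 1L) {
    sens <- stage("sensitivity",
                  model_sensitivity(state_tables, panel = panel,
                                    threshold = cfg$threshold))
    utils::write.table(sens$table, file.path(cfg$outdir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  smry <- list(
    package_version = as.character(utils::packageVersion("ancsr")),
    seed = cfg$seed,
    threshold = cfg$threshold,
    rare_max = cfg$rare_max,
    models = names(state_tables),
    node = unique(primary$node),
    n_panel_sites = nrow(panel),
    n_variable_sites = sum(vs$variable),
    variable_columns = as.integer(names(vs$variable)[vs$variable]),
    n_combinations = if (is.null(combos)) 0L else nrow(combos),
    min_joint = if (is.null(combos)) NA else min(combos$joint),
    max_joint = if (is.null(combos)) NA else max(combos$joint),
    min_joint_pct = if (is.null(combos)) NA else 100 * min(combos$joint),
    min_ratio_to_top_pct = if (is.null(combos)) NA else
      100 * min(combos$ratio_to_top)
  )
  if (!is.null(cls)) smry <- c(smry, cls$summary)
  jsonlite::write_json(smry, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(cfg[setdiff(names(cfg), c("alignment", "tree",
                                             "state_table", "panel"))],
                   file.path(cfg$outdir, "resolved_config.yaml"))

  invisible(list(state_tables = state_tables, variable = vs,
                 combos = combos, classification = cls,
                 co_occurrence = coocc, sensitivity = sens,
                 summary = smry, outdir = cfg$outdir))
}

#' Compare ancestral posteriors across substitution models
#'
#' For each panel site that is variable under at least one model, lists the
#' states above threshold per model with their posteriors and recoded
#' types, and flags sites where the most-probable residue differs between
#' models while the most-probable physicochemical type does not
#' (`residue_flip`), and sites where even the type differs (`type_flip`).
#' Flags are order-independent in the model list.
#'
#' @param state_tables Named list (>= 2) of [state_table]s for the same
#'   node and site set.
#' @param panel Optional [site_panel] restricting the sites compared;
#'   default all shared sites.
#' @param threshold Posterior cutoff for listing states (default 0.10).
#' @param scheme A [physchem_scheme()].
#' @return List of class `model_sensitivity`: `table` (site x model rows:
#'   listed states, top residue, top type) and `flags` (per site:
#'   `residue_flip`, `type_flip`).
#' @export
model_sensitivity <- function(state_tables, panel = NULL, threshold = 0.10,
                              scheme = physchem_scheme()) {
  if (length(state_tables) < 2L)
    stop("need at least two state tables")
  if (is.null(names(state_tables)) || any(!nzchar(names(state_tables))))
    names(state_tables) <- paste0("model", seq_along(state_tables))
  sites <- lapply(state_tables, function(st) sort(unique(st$site)))
  if (!all(vapply(sites[-1], identical, logical(1), sites[[1]])))
    stop("state tables cover different site sets")
  shared <- sites[[1]]
  if (!is.null(panel)) {
    miss <- setdiff(panel$column, shared)
    if (length(miss))
      stop("panel column(s) missing from state tables: ",
           paste(miss, collapse = ", "))
    shared <- panel$column
  }
  nodes <- vapply(state_tables, function(st) unique(st$node)[1], character(1))

  per_model <- function(st, node, site) {
    p <- state_probs(st, node, site)
    p <- sort(p[p > threshold], decreasing = TRUE)
    list(listed = p,
         top_residue = names(p)[1],
         top_type = suppressMessages(recode(names(p)[1], scheme)))
  }
  rows <- list()
  flags <- list()
  for (site in shared) {
    info <- mapply(per_model, state_tables, nodes,
                   MoreArgs = list(site = site), SIMPLIFY = FALSE)
    variable <- any(vapply(info, function(z) length(z$listed) >= 2L,
                           logical(1)))
    if (!variable) next
    for (nm in names(info)) {
      z <- info[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, model = nm,
        states = paste(sprintf("%s=%.5f", names(z$listed), z$listed),
                       collapse = ";"),
        types = paste(unique(suppressMessages(recode(names(z$listed),
                                                     scheme))),
                      collapse = ";"),
        top_residue = z$top_residue, top_type = z$top_type,
        stringsAsFactors = FALSE)
    }
    tr <- vapply(info, function(z) z$top_residue, character(1))
    tt <- vapply(info, function(z) z$top_type, character(1))
    flags[[length(flags) + 1L]] <- data.frame(
      site = site,
      residue_flip = length(unique(tr)) > 1L && length(unique(tt)) == 1L,
      type_flip = length(unique(tt)) > 1L,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows),
                 flags = do.call(rbind, flags),
                 threshold = threshold),
            class = "model_sensitivity")
}

#' @export
print.model_sensitivity <- function(x, ...) {
  cat(sprintf("model_sensitivity: %d variable site(s) compared at P > %g\n",
              nrow(x$flags), x$threshold))
  if (!is.null(x$flags)) {
    fl <- x$flags[x$flags$residue_flip | x$flags$type_flip, ]
    if (nrow(fl)) {
      for (i in seq_len(nrow(fl)))
        cat(sprintf("  site %d: %s\n", fl$site[i],
                    if (fl$type_flip[i]) "top TYPE differs between models"
                    else "top residue flips, type stable"))
    } else cat("  no argmax disagreements between models\n")
  }
  invisible(x)
}
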