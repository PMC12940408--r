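#' Assemble a pipeline run configuration
#'
#' Inputs may be file paths (PDB models, canonical variant TSVs,
#' stability TSV, annotation YAML) or in-memory objects of the matching
#' classes; mixing is allowed. A configuration hash and the seed are
#' stamped into every output.
#'
#' @param models character vector of three PDB paths or a
#'   [state_model_set()].
#' @param clinvar,gnomad canonical variant TSV paths or [variant_set()]s
#'   (either may be NULL).
#' @param stability stability TSV path or a stability table; NULL runs
#'   the mechanism stage in annotation-only (degraded) mode.
#' @param annotation annotation YAML path or an [annotation_config()].
#' @param out_dir output directory (created if missing).
#' @param n_permutations,alpha,seed hotspot-scan parameters.
#' @param hotspot_states states scanned for hotspots (default 1 and 3).
#' @param rules a [mechanism_rules()] list.
#' @return A `run_config` list.
#' @export
run_config <- function(models, clinvar = NULL, gnomad = NULL,
                       stability = NULL, annotation, out_dir,
                       n_permutations = 10000, alpha = 0.0001, seed = 1L,
                       hotspot_states = c(1, 3),
                       rules = mechanism_rules()) {
  for (x in list(models, clinvar, gnomad, stability, annotation)) {
    if (is.character(x) && !all(file.exists(x)))
      stop("missing input file(s): ",
           paste(x[!file.exists(x)], collapse = ", "), call. = FALSE)
  }
  structure(list(models = models, clinvar = clinvar, gnomad = gnomad,
                 stability = stability, annotation = annotation,
                 out_dir = out_dir, n_permutations = n_permutations,
                 alpha = alpha, seed = as.integer(seed),
                 hotspot_states = hotspot_states, rules = rules),
            class = "run_config")
}

config_hash <- function(cfg) {
  repr <- list(n_permutations = cfg$n_permutations, alpha = cfg$alpha,
               seed = cfg$seed, hotspot_states = cfg$hotspot_states,
               rules = cfg$rules,
               inputs = lapply(cfg[c("models", "clinvar", "gnomad",
                                     "stability", "annotation")],
                               function(x) if (is.character(x)) x else class(x)[1]))
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(repr, tf, auto_unbox = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full variant-interpretation pipeline
#'
#' Stage order: variant parsing/merging/filtering, residue-context
#' annotation, stability ingestion, 3D hotspot scan (both weightings
#' over the configured states), mechanism classification, ACMG evidence
#' and reclassification. Writes `context.tsv`, `hotspot.tsv`,
#' `mechanism.tsv`, `acmg.tsv`, `summary.json` and `run.log` into the
#' output directory; a stage failure leaves a `FAILED` marker naming the
#' stage and retains partial outputs.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  cat("config_hash=", hash, " seed=", cfg$seed, "\n", sep = "", file = logf)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, " -- ",
                      conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "variant_io"
    logline("stage variant_io")
    get_vs <- function(x, source) {
      if (is.null(x)) return(NULL)
      if (inherits(x, "variant_set")) return(x)
      parse_variant_rows(utils::read.table(x, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE),
                         source = source)
    }
    cv <- get_vs(cfg$clinvar, "clinvar")
    gn <- get_vs(cfg$gnomad, "gnomad")
    variants <- if (!is.null(cv) && !is.null(gn)) merge_sources(cv, gn)
      else cv %||% gn
    if (is.null(variants)) stop("no variant input configured")

    stage <- "structure_context"
    logline("stage structure_context")
    models <- if (inherits(cfg$models, "state_model_set")) cfg$models
      else load_state_models(cfg$models)
    variants <- restrict_to_model(variants, models$range[1], models$range[2])
    config <- if (inherits(cfg$annotation, "annotation_config")) cfg$annotation
      else read_annotation_config(cfg$annotation)
    maps <- lapply(cfg$hotspot_states, function(s)
      build_contact_map(models$models[[s]], 10))
    context <- build_residue_context(models, config, contact_map = maps[[1]])

    stage <- "biophysics"
    logline("stage biophysics")
    degraded <- is.null(cfg$stability)
    stability <- if (degraded) load_stability_table(data.frame())
      else if (inherits(cfg$stability, "data.frame") &&
               inherits(cfg$stability, "stability_table")) cfg$stability
      else load_stability_table(utils::read.table(cfg$stability,
                                                  header = TRUE, sep = "\t",
                                                  stringsAsFactors = FALSE))
    if (degraded) logline("no stability table: annotation-only rules")

    stage <- "hotspot3d"
    logline("stage hotspot3d")
    buckets <- partition_by_class(variants)
    scan_set <- buckets$pathogenic_or_lp
    hotspot_rows <- list(); hotspot_sets <- list()
    k <- 0L
    for (i in seq_along(maps)) {
      for (w in c("allele_count", "variant_count")) {
        k <- k + 1L
        prof <- suppressWarnings(permutation_pvalues(
          maps[[i]], scan_set, weighting = w,
          n_permutations = cfg$n_permutations,
          seed = cfg$seed + 101L * k))
        hs <- call_hotspots(prof, alpha = cfg$alpha)
        hotspot_sets[[k]] <- hs
        hotspot_rows[[k]] <- hotspot_table(prof, hs)
      }
    }
    hotspot_df <- do.call(rbind, hotspot_rows)
    hotspot_union <- sort(unique(unlist(lapply(hotspot_sets,
                                               function(h) h$members))))
    context$hotspot <- context$residue %in% hotspot_union

    stage <- "mechanism"
    logline("stage mechanism")
    calls <- classify_cohort(variants, context, stability, cfg$rules)

    stage <- "acmg"
    logline("stage acmg")
    path_pos <- split(buckets$pathogenic_or_lp$alt_aa,
                      as.character(buckets$pathogenic_or_lp$position))
    evidence <- list(); acmg_rows <- list()
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      j <- match(v$position, context$residue)
      ev <- assign_evidence(v, context[j, ], hotspot_union,
                            calls$category[i], path_pos)
      evidence[[v$hgvs_p]] <- ev
      call <- combine_acmg(ev)
      acmg_rows[[i]] <- data.frame(
        hgvs_p = v$hgvs_p, significance = v$significance,
        pm1 = ev[["PM1"]], pm2 = ev[["PM2"]], pm5 = ev[["PM5"]],
        pp3 = ev[["PP3"]], pp4 = ev[["PP4"]],
        combined_class = call$combined_class,
        satisfied_rule = call$satisfied_rule,
        lines_to_lp = call$lines_to_lp, stringsAsFactors = FALSE)
    }
    acmg_df <- do.call(rbind, acmg_rows)
    vus_keys <- variants$hgvs_p[variants$significance %in%
                                  c("vus", "unannotated", "conflicting")]
    report <- reclassification_report(
      variants, evidence[vus_keys],
      existing_plp_count = nrow(buckets$pathogenic_or_lp))

    stage <- "outputs"
    logline("stage outputs")
    wt <- function(df, name) {
      p <- file.path(cfg$out_dir, name)
      utils::write.table(cbind(df), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    }
    wt(as.data.frame(context), "context.tsv")
    wt(hotspot_df, "hotspot.tsv")
    wt(as.data.frame(calls), "mechanism.tsv")
    wt(acmg_df, "acmg.tsv")
    summary <- list(
      config_hash = hash, seed = cfg$seed,
      degraded_no_stability = degraded,
      n_variants = nrow(variants),
      class_counts = as.list(vapply(buckets, nrow, integer(1))),
      category_counts = as.list(table(calls$category)),
      hotspot_sizes = vapply(hotspot_sets,
                             function(h) length(h$members), integer(1)),
      hotspot_union_size = length(hotspot_union),
      n_reclassified = report$n_reclassified,
      n_one_away = report$n_one_away,
      percent_increase = report$percent_increase)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    logline("done")
    invisible(list(variants = variants, context = context,
                   stability = stability, hotspots = hotspot_sets,
                   hotspot_union = hotspot_union, calls = calls,
                   evidence = evidence, acmg = acmg_df, report = report,
                   summary = summary))
  }, error = on_fail)
}
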