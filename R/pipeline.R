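# End-to-end orchestration: a single structured config drives the
# stages (simulate -> triage -> lso -> coloc -> blot -> stats), each
# isolated so one failing stage does not poison the others, with a
# provenance block sufficient to re-execute the run.

CONFIG_SCHEMA_VERSION <- 1L

#' Read and validate a run configuration
#'
#' Accepts a list, a JSON file, or (when the \pkg{yaml} package is
#' available) a YAML file.  Top-level fields: \code{out_dir}
#' (required), optional \code{seed} (default 1) and one block per
#' requested stage: \code{simulate}, \code{triage}, \code{lso},
#' \code{coloc}, \code{blot}, \code{stats}.  All referenced input
#' paths must exist at validation time.
#'
#' @param config list or path to a JSON/YAML file.
#' @return validated config list (class \code{npcquant_config}).
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      abort_validation(sprintf("config file not found: %s", config))
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        abort_validation("YAML config requires the 'yaml' package")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) abort_validation("'config' must be a list or a path")
  if (is.null(config$out_dir))
    abort_validation("config lacks required field 'out_dir'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$schema_version)) config$schema_version <- CONFIG_SCHEMA_VERSION
  if (config$schema_version != CONFIG_SCHEMA_VERSION)
    abort_validation(sprintf("unsupported config schema version %s",
                             config$schema_version))
  known <- c("out_dir", "seed", "schema_version", "simulate", "triage",
             "lso", "coloc", "blot", "stats")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    abort_validation(paste0("unknown config field(s): ",
                            paste(unknown, collapse = ", ")))
  for (stage in c("triage", "lso", "coloc", "blot", "stats")) {
    blk <- config[[stage]]
    if (is.null(blk)) next
    for (fld in intersect(names(blk),
                          c("input", "manifest", "levels", "glycoforms",
                            "values"))) {
      p <- blk[[fld]]
      if (is.character(p) && !p %in% c("packaged", "simulated") &&
          !file.exists(p))
        abort_validation(sprintf("config %s$%s refers to a missing file: %s",
                                 stage, fld, p))
    }
  }
  class(config) <- c("npcquant_config", "list")
  config
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(ok = TRUE, result = fun()),
                  npcquant_error = function(e)
                    list(ok = FALSE, error = conditionMessage(e)),
                  error = function(e)
                    list(ok = FALSE, error = conditionMessage(e)))
  report$stages[[name]] <- res
  if (!res$ok)
    message(sprintf("[%s] stage failed: %s", name, res$error))
  report
}

#' Run the quantification pipeline from a config
#'
#' Executes the configured stages in dependency order (simulation
#' first, then triage, imaging, blot and statistics).  A stage failure
#' is recorded in the report as a structured error and does not affect
#' the remaining stages.  Stage outputs are written as CSV under
#' \code{out_dir}; the returned report carries every result table plus
#' a provenance block (config echo, package and R versions, seed,
#' timestamp).
#'
#' @param config list or path accepted by \code{\link{read_run_config}}.
#' @return object of class \code{npcquant_report}.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(),
                 provenance = list(
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("npcquant")),
                   r_version = R.version.string,
                   seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC")))

  sim_paths <- list()
  if (!is.null(config$simulate)) {
    report <- run_stage(report, "simulate", function() {
      sim <- config$simulate
      out <- list()
      if (isTRUE(sim$screen) || is.list(sim$screen)) {
        args <- if (is.list(sim$screen)) sim$screen else list()
        args$seed <- args$seed %||% config$seed
        tab <- gen_screen_table(do.call(screen_spec, args))
        p <- file.path(config$out_dir, "synthetic_screen.csv")
        utils::write.csv(tab, p, row.names = FALSE)
        sim_paths$screen <<- p
        out$screen <- p
      }
      if (isTRUE(sim$blot) || is.list(sim$blot)) {
        args <- if (is.list(sim$blot)) sim$blot else list()
        args$seed <- args$seed %||% config$seed
        ds <- gen_blot_dataset(do.call(blot_spec, args))
        p1 <- file.path(config$out_dir, "synthetic_blot_levels.csv")
        p2 <- file.path(config$out_dir, "synthetic_blot_glycoforms.csv")
        utils::write.csv(ds$levels, p1, row.names = FALSE)
        utils::write.csv(ds$glycoforms, p2, row.names = FALSE)
        sim_paths$blot <<- list(levels = p1, glycoforms = p2)
        out$blot <- c(p1, p2)
      }
      out
    })
  }

  if (!is.null(config$triage)) {
    report <- run_stage(report, "triage", function() {
      blk <- config$triage
      tab <- if (is.null(blk$input) || identical(blk$input, "packaged")) {
        npc_docking_table()
      } else if (!is.null(sim_paths$screen) &&
                 identical(blk$input, "simulated")) {
        read_compound_table(sim_paths$screen)
      } else read_compound_table(blk$input)
      crit <- hit_criterion(blk$reference_energy %||% -11.3)
      ranked <- rank_compounds(tab, crit)
      utils::write.csv(ranked, file.path(config$out_dir, "triage_report.csv"),
                       row.names = FALSE)
      list(table = ranked, n_hits = sum(ranked$is_hit),
           reference_energy = crit$reference_energy)
    })
  }

  if (!is.null(config$lso)) {
    report <- run_stage(report, "lso", function() {
      blk <- config$lso
      man <- utils::read.csv(blk$manifest, stringsAsFactors = FALSE)
      if (!all(c("field_id", "path") %in% names(man)))
        abort_validation("LSO manifest needs columns field_id, path")
      rows <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
        img <- read_tiff_gray(man$path[i])
        lso_compartment_ratio(img, blk$t_low, blk$t_high,
                              field_id = man$field_id[i])
      }))
      utils::write.csv(rows, file.path(config$out_dir, "lso_fields.csv"),
                       row.names = FALSE)
      list(fields = as.data.frame(rows), summary = aggregate_fields(rows))
    })
  }

  if (!is.null(config$coloc)) {
    report <- run_stage(report, "coloc", function() {
      blk <- config$coloc
      man <- utils::read.csv(blk$manifest, stringsAsFactors = FALSE)
      if (!all(c("field_id", "path_ch1", "path_ch2") %in% names(man)))
        abort_validation("coloc manifest needs field_id, path_ch1, path_ch2")
      rows <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
        m <- pearson_colocalization(read_tiff_gray(man$path_ch1[i]),
                                    read_tiff_gray(man$path_ch2[i]))
        cbind(field_id = man$field_id[i], as.data.frame(m))
      }))
      utils::write.csv(rows, file.path(config$out_dir, "coloc_fields.csv"),
                       row.names = FALSE)
      list(fields = rows)
    })
  }

  if (!is.null(config$blot)) {
    report <- run_stage(report, "blot", function() {
      blk <- config$blot
      lv_path <- blk$levels %||% sim_paths$blot$levels
      if (is.null(lv_path))
        abort_validation("blot stage needs 'levels' (or a simulated blot)")
      lanes <- utils::read.csv(lv_path, stringsAsFactors = FALSE)
      summ <- summarize_blot(lanes, control = blk$control %||% "DMSO")
      out <- list(conditions = summ$conditions)
      gf_path <- blk$glycoforms %||% sim_paths$blot$glycoforms
      if (!is.null(gf_path)) {
        g <- utils::read.csv(gf_path, stringsAsFactors = FALSE)
        fr <- cbind(g[c("lane_id", "condition")],
                    glycoform_fractions(g$endoH_R, g$endoH_S))
        utils::write.csv(fr, file.path(config$out_dir,
                                       "blot_glycoform_fractions.csv"),
                         row.names = FALSE)
        out$glycoforms <- fr
      }
      utils::write.csv(summ$conditions,
                       file.path(config$out_dir, "blot_conditions.csv"),
                       row.names = FALSE)
      out
    })
  }

  if (!is.null(config$stats)) {
    report <- run_stage(report, "stats", function() {
      blk <- config$stats
      df <- utils::read.csv(blk$values, stringsAsFactors = FALSE)
      res <- choose_and_run_test(df, control = blk$control,
                                 alpha_normality = blk$alpha_normality %||% 0.05)
      utils::write.csv(res$comparisons,
                       file.path(config$out_dir, "stats_comparisons.csv"),
                       row.names = FALSE)
      list(test_used = res$test_used, omnibus_p = res$omnibus_p,
           comparisons = res$comparisons)
    })
  }

  class(report) <- "npcquant_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to disk
#'
#' Emits a machine-readable JSON report (all stage tables plus
#' provenance) and, for each stage result table, a CSV.  Numeric
#' fields survive a write/read round trip exactly (JSON written at
#' full precision).
#'
#' @param report an \code{npcquant_report}.
#' @param dir output directory (created if needed).
#' @param formats subset of \code{c("json", "csv")}.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "csv")) {
  if (!inherits(report, "npcquant_report"))
    abort_validation("'report' must be an npcquant_report")
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    files["json"] <- p
  }
  if ("csv" %in% formats) {
    for (stage in names(report$stages)) {
      res <- report$stages[[stage]]
      if (!isTRUE(res$ok)) next
      tabs <- Filter(is.data.frame, res$result)
      for (nm in names(tabs)) {
        p <- file.path(dir, sprintf("report_%s_%s.csv", stage, nm))
        utils::write.csv(tabs[[nm]], p, row.names = FALSE)
        files[paste(stage, nm, sep = "_")] <- p
      }
    }
  }
  invisible(files)
}

#' @export
print.npcquant_report <- function(x, ...) {
  cat("npcquant pipeline report\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                if (isTRUE(s$ok)) "ok" else paste("FAILED:", s$error)))
  }
  invisible(x)
}
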