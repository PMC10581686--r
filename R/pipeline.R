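# End-to-end orchestration: simulate (or load) -> sample -> traits/design ->
# count models with diagnostic escalation -> variance partition -> imbalance
# scores -> report, with a manifest that makes reruns reproducible.

#' Pipeline configuration
#'
#' @param seed Integer; seeds every stage.
#' @param out_dir Output directory (created if missing).
#' @param simulate Generate inputs with the synthetic generator (`TRUE`,
#'   default) or read them from `profiles_file` (TSV following the
#'   [prepare_design()] column contract).
#' @param generator A [generator_config()]; its seed is overridden by `seed`.
#' @param taxonomy_shape For simulated runs: list with `n`, `n_phyla`,
#'   `n_classes`, `n_orders` passed to [gen_taxonomy()]. The default
#'   (`n = 1200`, 10/20/40) keeps a desk-scale run under a minute; scale up
#'   to the study's ~3000 species for production runs.
#' @param profiles_file Input TSV when `simulate = FALSE`.
#' @param alpha Significance level convention (default 0.01).
#' @param phylum_subsets Character vector of phyla for within-phylum
#'   (variant `"eq2"`) subset models; empty for none.
#' @param verbose Emit per-stage log lines (stage, seed, elapsed seconds).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("biointerest_run_"),
                            simulate = TRUE,
                            generator = generator_config(seed = seed),
                            taxonomy_shape = list(n = 1200L, n_phyla = 10L,
                                                  n_classes = 20L,
                                                  n_orders = 40L),
                            profiles_file = NULL,
                            alpha = 0.01,
                            phylum_subsets = character(0),
                            verbose = FALSE) {
  if (!simulate && is.null(profiles_file))
    stop("profiles_file required when simulate = FALSE")
  stopifnot(alpha > 0, alpha < 1)
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, generator = generator,
                 taxonomy_shape = taxonomy_shape,
                 profiles_file = profiles_file, alpha = alpha,
                 phylum_subsets = phylum_subsets, verbose = verbose),
            class = "pipeline_config")
}

.stage_log <- function(cfg, stage, t0) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] seed=%d elapsed=%.1fs", stage, cfg$seed,
                    as.numeric(Sys.time()) - t0))
}

.config_snapshot <- function(cfg) {
  snap <- cfg
  snap$generator <- unclass(snap$generator)
  snap$generator$beta_sci <- as.list(snap$generator$beta_sci)
  snap$generator$beta_pop <- as.list(snap$generator$beta_pop)
  snap$generator$trait_prevalences <-
    as.list(snap$generator$trait_prevalences)
  snap$generator$domain_probs <- as.list(snap$generator$domain_probs)
  snap$generator$iucn_probs <- as.list(snap$generator$iucn_probs)
  unclass(snap)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain species profiles (synthetic generator or file);
#' build the model-ready design; fit the scientific-interest model with
#' diagnostic escalation (Poisson, then NB2 once the overdispersion check
#' fires); fit the societal-interest model likewise, escalating further to
#' zero-inflated NB2 when the zero check underfits (ratio < 0.9) and keeping
#' whichever of NB2/ZINB2 wins on AIC; variance partition for both
#' responses; per-species imbalance scores and the Gaussian residual mixed
#' model; optional within-phylum subset models; and a manifest tying outputs
#' to inputs. A stage failure aborts with the stage name; outputs written so
#' far are kept with a `.partial` marker file.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `run_manifest` (also written as
#'   `manifest.json`): config snapshot, seed, input digests, per-stage
#'   output paths, package version. The fitted objects are attached as
#'   attribute `"results"` for interactive use.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  outputs <- list()
  stage <- "init"
  partial_marker <- file.path(cfg$out_dir, ".partial")
  file.create(partial_marker)
  on.exit({
    if (file.exists(partial_marker))
      message("pipeline aborted in stage '", stage,
              "'; partial outputs retained in ", cfg$out_dir)
  })

  run_stage <- function(name, expr) {
    stage <<- name
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .stage_log(cfg, name, t0)
    out
  }

  profiles <- run_stage("profiles", {
    if (cfg$simulate) {
      ts <- cfg$taxonomy_shape
      tx <- gen_taxonomy(ts$n, ts$n_phyla, ts$n_classes, ts$n_orders,
                         seed = cfg$seed)
      gen_profiles(tx, cfg$generator)
    } else {
      utils::read.table(cfg$profiles_file, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
  })
  outputs$profiles <- file.path(cfg$out_dir, "profiles.tsv")
  utils::write.table(profiles, outputs$profiles, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  des <- run_stage("design", prepare_design(profiles, variant = "eq1"))

  fit_with_escalation <- function(response) {
    pois <- fit_count_model(des, spec = count_model_spec(response, "poisson"))
    od <- overdispersion_check(pois)
    family <- if (od$dispersion_ratio > 1.5) "nb2" else "poisson"
    fit <- if (family == "nb2")
      fit_count_model(des, spec = count_model_spec(response, "nb2"))
    else pois
    zc <- zero_check(fit)
    escalated <- FALSE
    if (!is.na(zc$zero_ratio) && zc$zero_ratio < 0.9) {
      zfit <- fit_count_model(des, spec = count_model_spec(response, "zinb2"))
      if (zfit$converged && zfit$aic < fit$aic) {
        fit <- zfit
        escalated <- TRUE
      }
    }
    list(fit = fit, poisson_overdispersion = od, zero_check = zc,
         zero_escalated = escalated)
  }

  sci <- run_stage("fit_papers", fit_with_escalation("papers"))
  pop <- run_stage("fit_views", fit_with_escalation("views"))

  for (nm in c("papers", "views")) {
    f <- if (nm == "papers") sci$fit else pop$fit
    outputs[[paste0("forest_", nm)]] <-
      file.path(cfg$out_dir, paste0("forest_", nm, ".tsv"))
    utils::write.table(coef_table(f, cfg$alpha),
                       outputs[[paste0("forest_", nm)]],
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  outputs$diagnostics <- file.path(cfg$out_dir, "diagnostics.json")
  jsonlite::write_json(list(
    papers = c(sci$poisson_overdispersion[c("dispersion_ratio",
                                            "pearson_chi2", "df")],
               sci$zero_check[c("observed_zeros", "predicted_zeros",
                                "zero_ratio")],
               list(family = sci$fit$family, aic = sci$fit$aic,
                    vif_max = max(vif(des)))),
    views = c(pop$poisson_overdispersion[c("dispersion_ratio",
                                           "pearson_chi2", "df")],
              pop$zero_check[c("observed_zeros", "predicted_zeros",
                               "zero_ratio")],
              list(family = pop$fit$family, aic = pop$fit$aic))),
    outputs$diagnostics, auto_unbox = TRUE, digits = NA, na = "null")

  parts <- run_stage("partition", {
    lapply(c(papers = "papers", views = "views"), function(resp) {
      fam <- if (resp == "papers") sci$fit$family else pop$fit$family
      variance_partition(des, spec = count_model_spec(resp, fam))
    })
  })
  outputs$partition <- file.path(cfg$out_dir, "partition.json")
  jsonlite::write_json(lapply(parts, function(p)
    p[c("r2m_full", "r2c_full", "unique_species", "unique_culture",
        "shared", "random_component", "unexplained")]),
    outputs$partition, auto_unbox = TRUE, digits = NA)

  imb <- run_stage("imbalance", {
    sc <- imbalance_scores(des)
    lmm <- fit_residual_lmm(sc, des)
    list(scores = sc, lmm = lmm)
  })
  outputs$scores <- file.path(cfg$out_dir, "imbalance_scores.tsv")
  utils::write.table(imb$scores, outputs$scores, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  outputs$smooth <- file.path(cfg$out_dir, "smooth.json")
  sm <- attr(imb$scores, "smooth")
  jsonlite::write_json(list(lambda = sm$lambda, edf = sm$edf, gcv = sm$gcv,
                            basis_size = sm$basis_size),
                       outputs$smooth, auto_unbox = TRUE, digits = NA)
  outputs$forest_residual <- file.path(cfg$out_dir, "forest_residual.tsv")
  utils::write.table(coef_table(imb$lmm, cfg$alpha), outputs$forest_residual,
                     sep = "\t", row.names = FALSE, quote = FALSE)

  subsets <- NULL
  if (length(cfg$phylum_subsets)) {
    subsets <- run_stage("phylum_subsets", {
      lapply(stats::setNames(cfg$phylum_subsets, cfg$phylum_subsets),
             function(ph) {
        rows <- profiles$phylum == ph
        if (!any(rows)) stop("phylum absent from data: ", ph)
        sub <- prepare_design(profiles[rows, , drop = FALSE], variant = "eq2")
        fit_count_model(sub, spec = count_model_spec("papers", "nb2",
                                                     variant = "eq2"))
      })
    })
    for (ph in names(subsets)) {
      key <- paste0("forest_eq2_", ph)
      outputs[[key]] <- file.path(cfg$out_dir,
                                  paste0("forest_eq2_", ph, ".tsv"))
      utils::write.table(coef_table(subsets[[ph]], cfg$alpha),
                         outputs[[key]], sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }

  stage <- "manifest"
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("biointerest")),
    seed = cfg$seed,
    config = .config_snapshot(cfg),
    input_digests = if (!cfg$simulate)
      as.list(tools::md5sum(cfg$profiles_file)) else list(),
    output_digests = as.list(tools::md5sum(unlist(outputs))),
    outputs = outputs), class = "run_manifest")
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$path <- manifest_path
  file.remove(partial_marker)
  on.exit()
  attr(manifest, "results") <- list(design = des, sci = sci, pop = pop,
                                    partition = parts, imbalance = imb,
                                    subsets = subsets)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("biointerest run (seed", x$seed, ", package",
      x$package_version, ")\n")
  cat("outputs:\n")
  for (nm in names(x$outputs)) cat("  ", nm, ": ", x$outputs[[nm]], "\n",
                                   sep = "")
  invisible(x)
}

#' Build a human-readable report from a run manifest
#'
#' Re-reads the stage outputs named in the manifest and assembles summary
#' tables: coefficient forest data for both responses and the residual
#' model, partition shares, the top species by absolute imbalance residual,
#' and diagnostics. Regenerating the report from the same manifest is
#' byte-identical.
#'
#' @param manifest A [run_pipeline()] result or the path to a
#'   `manifest.json`.
#' @param top_n Rows in the top-|residual| table (default 20).
#' @return Object of class `run_report`: list of data.frames/lists.
#' @export
build_report <- function(manifest, top_n = 20L) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  out <- manifest$outputs
  need <- c("forest_papers", "forest_views", "forest_residual",
            "partition", "scores", "diagnostics")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("manifest missing stage outputs: ",
                         paste(miss, collapse = ", "))
  gone <- unlist(out[need])[!file.exists(unlist(out[need]))]
  if (length(gone)) stop("stage output files missing: ",
                         paste(gone, collapse = ", "))
  read_tsv <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
  scores <- read_tsv(out$scores)
  top <- scores[order(abs(scores$residual), decreasing = TRUE), ]
  top <- utils::head(top, top_n)
  rownames(top) <- NULL
  part <- jsonlite::read_json(out$partition, simplifyVector = TRUE)
  structure(list(
    forest_papers = read_tsv(out$forest_papers),
    forest_views = read_tsv(out$forest_views),
    forest_residual = read_tsv(out$forest_residual),
    partition = part,
    top_residuals = top,
    diagnostics = jsonlite::read_json(out$diagnostics,
                                      simplifyVector = TRUE),
    seed = manifest$seed), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== biointerest report (seed", x$seed, ") ==\n\n")
  cat("Scientific-interest model:\n")
  print(x$forest_papers, row.names = FALSE)
  cat("\nSocietal-interest model:\n")
  print(x$forest_views, row.names = FALSE)
  cat("\nVariance partition:\n")
  print(as.data.frame(x$partition))
  cat("\nTop species by |imbalance residual|:\n")
  print(utils::head(x$top_residuals, 10), row.names = FALSE)
  invisible(x)
}
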