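#' Pipeline configuration
#'
#' Collects everything needed for a full analysis run: input location and
#' column mapping, part order and closure constant, ilr basis, the outcome
#' models to fit, substitution grid durations, grouping column, zero policy
#' and seed.
#'
#' @param input Path to the records file (see [read_records()]).
#' @param output_dir Directory for the report bundle (created if needed).
#' @param models Named list: for each outcome to model, a character vector of
#'   covariates. Default: zBMI and \%WHtR on sex + age + IMD decile; VO2 peak
#'   on those, and again with zBMI added.
#' @param durations Substitution grid durations in minutes; default 0-25 by
#'   5. Use `seq(0, 25, by = 2.5)` for the fine grid.
#' @param substitution_minutes Duration for the square substitution matrices
#'   (default 15).
#' @param group_col Grouping column for group-baseline grids (`NULL` to
#'   skip); default `"weight_status"`.
#' @param basis ilr basis; `NULL` for the pivot default over `part_cols`.
#' @param part_cols,kappa See [record_compositions()].
#' @param col_map,zero_policy,delta Passed to [read_records()].
#' @param seed Seed recorded in, and used by, the run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, output_dir,
                            models = list(
                              zbmi = c("sex", "age", "imd_decile"),
                              whtr_pct = c("sex", "age", "imd_decile"),
                              vo2peak = c("sex", "age", "imd_decile"),
                              vo2peak_zbmi_adjusted = c("sex", "age", "imd_decile", "zbmi")
                            ),
                            durations = seq(0, 25, by = 5),
                            substitution_minutes = 15,
                            group_col = "weight_status",
                            basis = NULL,
                            part_cols = default_part_cols(),
                            kappa = 1440,
                            col_map = NULL,
                            zero_policy = "error", delta = 0.5,
                            seed = 1L) {
  if (kappa <= 0) stop("kappa must be positive")
  if (any(durations < 0)) stop("durations must be nonnegative")
  structure(list(
    input = input, output_dir = output_dir, models = models,
    durations = durations, substitution_minutes = substitution_minutes,
    group_col = group_col,
    basis = resolve_basis(basis, names(part_cols)),
    part_cols = part_cols, kappa = kappa, col_map = col_map,
    zero_policy = zero_policy, delta = delta, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# Outcome column for a model entry: "vo2peak_zbmi_adjusted" models vo2peak
# with zbmi among the covariates; anything else names its own column.
model_outcome_col <- function(name) sub("_zbmi_adjusted$", "", name)

pipeline_log <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE)
}

write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full compositional analysis pipeline
#'
#' Executes three stages on the input table and writes a report bundle:
#' \describe{
#'   \item{describe}{compositional means (full sample and per group) and the
#'     pairwise log-ratio variation matrix.}
#'   \item{fit}{each configured ilr linear model: coefficient table, Type II
#'     ANOVA table, diagnostics summary.}
#'   \item{substitute}{per model: the substitution matrix at
#'     `substitution_minutes`, the full difference grid over `durations` at
#'     the sample mean baseline, and group-baseline grids.}
#' }
#' Outputs are CSV tables plus a single `report.json`, and a `manifest.json`
#' recording package version, seed, the sign matrix of the ilr basis, part
#' order, kappa, and which stages completed. All outputs are deterministic
#' for a fixed configuration; timestamps go only to `pipeline.log`. A stage
#' failure writes the manifest (marking the stages that completed) and then
#' rethrows the error.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the report list (also serialised to `report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "movecoda",
    version = as.character(utils::packageVersion("movecoda")),
    seed = cfg$seed,
    parts = cfg$basis$parts,
    kappa = cfg$kappa,
    sbp = unclass(cfg$basis$sbp),
    zero_policy = cfg$zero_policy,
    durations = cfg$durations,
    stages_completed = character()
  )
  report <- list(seed = cfg$seed, parts = cfg$basis$parts, kappa = cfg$kappa)
  finish_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  run_stage <- function(name, fun) {
    pipeline_log(cfg$output_dir, paste("stage:", name))
    tryCatch(fun(), error = function(e) {
      pipeline_log(cfg$output_dir, sprintf("stage '%s' FAILED: %s", name, conditionMessage(e)))
      finish_manifest()
      stop(e)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
  }

  records <- NULL
  models <- list()

  run_stage("read", function() {
    records <<- read_records(cfg$input, cfg$col_map, zero_policy = cfg$zero_policy,
                             delta = cfg$delta, part_cols = cfg$part_cols)
    report$n_records <<- nrow(records)
    report$n_rejected <<- length(unique(attr(records, "validation")$row[
      grepl("rejected", attr(records, "validation")$action)]))
  })

  run_stage("describe", function() {
    comp <- record_compositions(records, cfg$part_cols, cfg$kappa)
    cm <- comp_mean(comp, cfg$kappa)
    vm <- variation_matrix(comp)
    means_tab <- data.frame(sample = "all", n = nrow(comp), t(cm))
    if (!is.null(cfg$group_col) && cfg$group_col %in% names(records)) {
      for (g in sort(unique(as.character(records[[cfg$group_col]])))) {
        sub <- comp[as.character(records[[cfg$group_col]]) == g, , drop = FALSE]
        means_tab <- rbind(means_tab,
                           data.frame(sample = g, n = nrow(sub), t(comp_mean(sub, cfg$kappa))))
      }
    }
    write_table(means_tab, cfg$output_dir, "compositional_means")
    vm_df <- data.frame(part = rownames(vm), vm, check.names = FALSE)
    write_table(vm_df, cfg$output_dir, "variation_matrix")
    report$compositional_means <<- means_tab
    report$variation_matrix <<- vm
  })

  run_stage("fit", function() {
    for (nm in names(cfg$models)) {
      out_col <- model_outcome_col(nm)
      fit <- fit_outcome_model(records, out_col, cfg$models[[nm]],
                               basis = cfg$basis, part_cols = cfg$part_cols,
                               kappa = cfg$kappa)
      an <- anova_marginality(fit)
      di <- model_diagnostics(fit)
      coefs <- data.frame(term = names(coef(fit)), estimate = unname(coef(fit)),
                          se = sqrt(diag(vcov(fit))))
      write_table(coefs, cfg$output_dir, paste0("model_", nm, "_coefficients"))
      write_table(as.data.frame(an), cfg$output_dir, paste0("model_", nm, "_anova"))
      models[[nm]] <<- fit
      report$models[[nm]] <<- list(
        outcome = out_col, covariates = cfg$models[[nm]],
        n = fit$n, n_dropped = fit$n_dropped,
        coefficients = coefs, anova = as.data.frame(an),
        diagnostics = list(
          normality_p = di$normality$p_value,
          homoscedasticity_p = di$homoscedasticity$p_value,
          linearity_p = di$linearity$p_value,
          n_outliers = length(di$outliers$flagged))
      )
    }
  })

  run_stage("substitute", function() {
    for (nm in names(models)) {
      fit <- models[[nm]]
      sm <- substitution_matrix(fit, minutes = cfg$substitution_minutes)
      write_table(data.frame(receives = rownames(sm), sm, check.names = FALSE),
                  cfg$output_dir, paste0("substitution_", nm,
                                         "_", cfg$substitution_minutes, "min"))
      grid <- difference_grid(fit, durations = cfg$durations)
      write_table(grid, cfg$output_dir, paste0("grid_", nm))
      report$substitution[[nm]] <<- list(
        baseline = as.list(attr(sm, "baseline")),
        minutes = cfg$substitution_minutes,
        matrix = sm, grid = grid)
      if (!is.null(cfg$group_col) && cfg$group_col %in% names(records)) {
        gg <- group_baseline_grids(fit, records, cfg$group_col, cfg$durations)
        for (g in names(gg)) {
          write_table(gg[[g]], cfg$output_dir, paste0("grid_", nm, "_", g))
          report$substitution[[nm]]$groups[[g]] <<-
            list(baseline = as.list(attr(gg[[g]], "baseline")), grid = gg[[g]])
        }
      }
    }
  })

  finish_manifest()
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  pipeline_log(cfg$output_dir, "pipeline complete")
  invisible(report)
}
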