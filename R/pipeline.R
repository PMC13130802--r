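#' Read a pipeline configuration file
#'
#' YAML is the native format; JSON is accepted (by extension). See
#' [run_pipeline()] for the recognised sections.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep single-letter y/n usable as column names (YAML 1.1 booleans)
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
      "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE
    ))
  }
}

stage_error <- function(stage, parent) {
  stop(structure(
    class = c(paste0("mediaopt_", stage, "_error"), "mediaopt_stage_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s", stage, conditionMessage(parent)),
         call = NULL, stage = stage)
  ))
}

log_jsonl <- function(con, ...) {
  writeLines(jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                   ...), auto_unbox = TRUE), con)
}

parse_factor_list <- function(lst) {
  lapply(lst, function(f) {
    factor_spec(f$name, kind = f$kind %||% "continuous",
                min = f$min, max = f$max,
                levels = if (!is.null(f$levels)) unlist(f$levels),
                units = f$units %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_constraints <- function(lst) {
  lapply(lst %||% list(), function(cn) {
    if ((cn$type %||% "single_bound") == "sum_bound") {
      constraint_sum(unlist(cn$variables), cn$bound, cn$sense %||% "<=",
                     cn$weight %||% 1)
    } else {
      constraint_single(cn$variable %||% unlist(cn$variables)[1], cn$bound,
                        cn$sense %||% "<=", cn$weight %||% 1)
    }
  })
}

#' Run the five-stage optimization pipeline
#'
#' Executes the requested stages in order design -> check -> train ->
#' optimize -> evaluate, writing every artifact plus a replayable run
#' manifest into `out_dir`. All randomness flows from exactly two seeds:
#' `seed_ml` (splitting, cross-validation, model fits) and `seed_ea`
#' (population initialization and variation), so replaying a manifest
#' reproduces the artifacts. A stage failure aborts the run with a
#' classed condition (`mediaopt_<stage>_error`); artifacts of completed
#' stages are preserved. No data leaves the machine.
#'
#' Config sections (all optional except the stages you request):
#' `data` (CSV path), `roles` (column -> A/B/C/D), `directions`
#' (response -> maximize/minimize), `design` (type, factors,
#' replicates, alpha, n_runs, max_replicates), `check`
#' (iqr_multiplier, cor_threshold), `train` (fraction, cv k/repeats,
#' algorithms, responses), `optimize` (algorithm, mu, lambda,
#' generations, extrapolation, cache, constraints), `evaluate`,
#' `seed_ml`, `seed_ea`, `stages`.
#'
#' @param config A named list or a path to a YAML/JSON file.
#' @param out_dir Artifact directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = "mediaopt-run") {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "events.jsonl"), open = "a")
  on.exit(close(log_con))

  seed_ml <- config$seed_ml %||% 1L
  seed_ea <- config$seed_ea %||% 1L
  stages <- config$stages %||%
    intersect(c("design", "check", "train", "optimize", "evaluate"),
              names(config))
  if (length(stages) == 0L) stop("no stages requested", call. = FALSE)
  manifest <- list(
    tool = paste0("mediaopt ", as.character(utils::packageVersion("mediaopt"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed_ml = seed_ml, seed_ea = seed_ea, stages = stages,
    config = config[setdiff(names(config), "stages")]
  )
  if (!is.null(config$data) && file.exists(config$data)) {
    manifest$input_md5 <- unname(tools::md5sum(config$data))
  }
  state <- list()

  run_stage <- function(stage, fn) {
    log_jsonl(log_con, stage = stage, event = "start")
    res <- tryCatch(fn(), error = function(e) stage_error(stage, e))
    log_jsonl(log_con, stage = stage, event = "done")
    res
  }

  if ("design" %in% stages) {
    state$design <- run_stage("design", function() {
      dc <- config$design
      factors <- parse_factor_list(dc$factors)
      d <- switch(tolower(dc$type %||% "ffd"),
        ffd = design_ffd(factors, dc$replicates %||% 1L),
        ccd = design_ccd(factors, alpha = dc$alpha %||% 0.8,
                         replicates = dc$replicates %||% 1L),
        bbd = design_bbd(factors, replicates = dc$replicates %||% 1L),
        lhs = design_lhs(factors, n_runs = dc$n_runs, seed = seed_ml),
        rd = design_random(factors, replicates = dc$replicates %||% 1L,
                           seed = seed_ml),
        stop("unknown design type: ", dc$type)
      )
      d <- cleanup_replicates(d, dc$max_replicates %||% 5L)
      write_design(d, file.path(out_dir, "design.csv"),
                   coded_path = file.path(out_dir, "design_coded.csv"))
      d
    })
  }

  needs_data <- intersect(c("check", "train", "optimize", "evaluate"), stages)
  if (length(needs_data)) {
    state$data <- run_stage("check", function() {
      if (is.null(config$data)) stop("config$data (CSV path) is required")
      utils::read.csv(config$data, check.names = FALSE)
    })
    roles <- unlist(config$roles) %||% NULL
    state$classification <- run_stage("check", function() {
      classify_variables(state$data, roles = roles)
    })
  }

  if ("check" %in% stages) {
    state$check <- run_stage("check", function() {
      cc <- config$check %||% list()
      cleaned <- drop_incomplete_rows(state$data)
      qr <- health_check(cleaned, state$classification,
                         iqr_multiplier = cc$iqr_multiplier %||% 1.5,
                         cor_threshold = cc$cor_threshold %||% 0.8)
      enc <- encode_categoricals(cleaned, state$classification)
      utils::write.csv(enc$data, file.path(out_dir, "cleaned.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(dropped_rows = attr(cleaned, "dropped"),
             missing = as.list(qr$missing),
             collinear = qr$collinear, warnings = qr$warnings),
        file.path(out_dir, "quality_report.json"), auto_unbox = TRUE,
        digits = NA)
      jsonlite::write_json(unclass(enc$map),
                           file.path(out_dir, "encoding_map.json"),
                           auto_unbox = FALSE)
      list(cleaned = enc$data, map = enc$map, report = qr)
    })
  }

  model_data <- if (!is.null(state$check)) state$check$cleaned else state$data

  if ("train" %in% stages) {
    state$train <- run_stage("train", function() {
      tc <- config$train %||% list()
      sp <- split_data(model_data, fraction = tc$fraction %||% 0.75,
                       seed = seed_ml)
      cv <- cv_control(k = tc$cv$k %||% 5L, repeats = tc$cv$repeats %||% 3L,
                       loocv = tc$cv$loocv %||% "auto")
      sc <- spot_check(sp$train, sp$test, state$classification,
                       responses = tc$responses %||% NULL,
                       algorithms = tc$algorithms %||% setdiff(ALGORITHMS, "ESR"),
                       cv = cv, seed = seed_ml)
      utils::write.csv(tidy(sc), file.path(out_dir, "model_metrics.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(seed_ml = seed_ml, cv = unclass(cv),
                                n_train = nrow(sp$train), n_test = nrow(sp$test),
                                predictors = sc$predictors,
                                dropped_predictors = sc$dropped_predictors),
                           file.path(out_dir, "train_metadata.json"),
                           auto_unbox = TRUE, digits = NA)
      list(split = sp, spot_check = sc)
    })
  }

  if ("optimize" %in% stages) {
    state$optimize <- run_stage("optimize", function() {
      oc <- config$optimize %||% list()
      sc <- state$train$spot_check
      if (is.null(sc)) stop("optimize requires the train stage")
      responses <- roles_of(state$classification, "D")
      models <- stats::setNames(lapply(responses, function(r) select_best(sc, r)),
                                responses)
      objectives <- objectives_from_models(models, model_data,
                                           directions = unlist(config$directions))
      space <- extract_bounds(model_data, state$classification,
                              extrapolation = oc$extrapolation %||% 0)
      problem <- surrogate_problem(objectives, space,
                                   constraints = parse_constraints(oc$constraints),
                                   cache = oc$cache %||% TRUE)
      control <- ea_control(toupper(oc$algorithm %||% "NSGA2"),
                            mu = oc$mu %||% 50L, lambda = oc$lambda %||% NULL,
                            generations = oc$generations %||% 100L,
                            seed = seed_ea)
      res <- switch(control$algorithm,
                    GA = run_ga(problem, control),
                    PSO = run_pso(problem, control),
                    NSGA2 = run_nsga2(problem, control),
                    SMSEMOA = run_smsemoa(problem, control))
      sols <- res$solutions
      if (!is.null(state$check$map) && length(state$check$map)) {
        sols <- decode_categoricals(sols, state$check$map)
      }
      utils::write.csv(sols, file.path(out_dir, "solutions.csv"),
                       row.names = FALSE)
      utils::write.csv(res$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(algorithm = control$algorithm, seed_ea = seed_ea,
             evaluations = res$evaluations, cache_hits = res$cache_hits,
             solutions = res$solutions),
        file.path(out_dir, "pareto.json"), auto_unbox = TRUE, digits = NA)
      list(result = res, objectives = objectives, problem = problem)
    })
  }

  if ("evaluate" %in% stages) {
    state$evaluate <- run_stage("evaluate", function() {
      if (is.null(state$optimize)) stop("evaluate requires the optimize stage")
      rep <- compare_solutions(model_data, state$optimize$result$solutions,
                               state$optimize$objectives)
      utils::write.csv(tidy(rep), file.path(out_dir, "evaluation.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(per_objective = rep$per_objective,
                                improvement = rep$improvement),
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    })
  }

  manifest$artifacts <- setdiff(list.files(out_dir), "manifest.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(state, list(manifest = manifest)))
}
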