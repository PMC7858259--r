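# 12 significant digits: enough that parsing a report recovers the value
# to the documented tolerance, stable across platforms
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) if (v > 0) "Inf" else "-Inf"
    else formatC(v, digits = 12, format = "g")
  }, character(1))
}

write_tsv_report <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a game and write decision reports
#'
#' Runs [evaluate_all()] and writes the report as TSV (one row per policy:
#' name, risk in bits, expected-utility term, entropy term, selected flag)
#' and/or JSON (full structure including the tie flag and stress
#' explanation). Identical inputs produce byte-identical outputs.
#'
#' @param game A [game_spec()], or a path to a JSON game config.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the report files (default `"decision"`).
#' @param format `"tsv"`, `"json"`, or `"both"`.
#' @param quiet Suppress the log line naming the selected policy.
#' @return The [evaluate_all()] report, invisibly.
#' @export
run_evaluate <- function(game, out_dir = ".", name = "decision",
                         format = c("both", "tsv", "json"), quiet = FALSE) {
  format <- match.arg(format)
  if (is.character(game)) game <- load_game(game)
  stopifnot(inherits(game, "game_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- evaluate_all(game)
  stress <- detect_stress(report)
  if (format %in% c("both", "tsv")) {
    write_tsv_report(as.data.frame(report),
                     file.path(out_dir, paste0(name, ".tsv")))
  }
  if (format %in% c("both", "json")) {
    jsonlite::write_json(list(
      agent_id = game$agent_id,
      evaluations = lapply(report$evaluations, unclass),
      selected = report$selected,
      tie = report$tie,
      tie_members = as.list(report$tie_members),
      stress = stress$stress,
      explanation = stress$explanation
    ), file.path(out_dir, paste0(name, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "string")
  }
  if (!quiet) {
    message(sprintf("[evaluate] %s | stress=%s", stress$explanation,
                    stress$stress))
  }
  invisible(report)
}

#' Sweep the exploitation preference and write curve/cutoff reports
#'
#' Runs [sweep_exploitation()] and writes the risk curves as a plot-ready
#' TSV (parameter value, per-state exploitation probability, one risk
#' column per policy) plus the cut-off estimate as JSON (null when no
#' crossing lies inside the grid).
#'
#' @inheritParams run_evaluate
#' @inheritParams sweep_exploitation
#' @param name Basename for the report files (default `"sweep"`).
#' @return The [sweep_exploitation()] result, invisibly.
#' @export
run_sweep <- function(game, grid, out_dir = ".",
                      parameter = "exploitation_reward",
                      cutoff_pair = NULL, name = "sweep",
                      format = c("both", "tsv", "json"), quiet = FALSE) {
  format <- match.arg(format)
  if (is.character(game)) game <- load_game(game)
  stopifnot(inherits(game, "game_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sw <- sweep_exploitation(game, grid, parameter = parameter,
                           cutoff_pair = cutoff_pair)
  if (format %in% c("both", "tsv")) {
    df <- sw$curves
    df <- cbind(df[1L], exploit_probability = sw$exploit_probability,
                df[-1L])
    write_tsv_report(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  if (format %in% c("both", "json")) {
    jsonlite::write_json(
      if (is.null(sw$cutoff)) list(cutoff = NULL) else
        list(cutoff = unclass(sw$cutoff)),
      file.path(out_dir, paste0(name, "_cutoff.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  if (!quiet) {
    message(sprintf("[sweep] %s over [%g, %g]: %s", sw$parameter_name,
                    min(grid), max(grid),
                    if (is.null(sw$cutoff)) "no crossing in grid"
                    else sprintf("cutoff at %.6g", sw$cutoff$parameter_value)))
  }
  invisible(sw)
}

#' Generate a random game and write its config
#'
#' Runs [generate_random_game()] and writes the resulting game as a JSON
#' config that [load_game()] reads back identically. The logged seed allows
#' exact regeneration.
#'
#' @inheritParams generate_random_game
#' @param path Output config path.
#' @param quiet Suppress the log line.
#' @return The generated [game_spec()], invisibly.
#' @export
run_generate <- function(seed, path, n_ego_actions = 3, n_alter_actions = 3,
                         reward_concentration = 1, floor = 1e-6,
                         quiet = FALSE) {
  game <- generate_random_game(seed, n_ego_actions, n_alter_actions,
                               reward_concentration, floor)
  write_game(game, path)
  if (!quiet) {
    message(sprintf("[generate] seed=%d -> %s (%dx%d actions)", seed, path,
                    n_ego_actions, n_alter_actions))
  }
  invisible(game)
}
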