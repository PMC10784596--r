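#' Rank landmarks by registration error
#'
#' Labels sorted by per-landmark Euclidean error, largest first; ties broken
#' by the lower label.
#'
#' @param fit A `cochlear_registration` object (or any object with an
#'   `errors` tibble of `label` and `error_mm`).
#' @return Integer vector of labels, worst landmark first.
#' @export
rank_by_error <- function(fit) {
  e <- fit$errors
  e$label[order(-e$error_mm, e$label)]
}

#' Percent error reduction
#'
#' The relative MAE improvement `100 * (1 - mae_new / mae_old)`, rounded to
#' two decimals.
#'
#' @param mae_old,mae_new MAE values in mm; `mae_old` must be positive.
#' @return Percent reduction (negative if the error grew).
#' @examples
#' reduction_percent(0.2383, 0.2307)  # 3.19
#' @export
reduction_percent <- function(mae_old, mae_new) {
  if (!is.finite(mae_old) || mae_old <= 0) {
    stop("`mae_old` must be strictly positive", call. = FALSE)
  }
  round(100 * (1 - mae_new / mae_old), 2)
}

#' Iterative worst-landmark pruning
#'
#' Reproduces the case-study workflow: register, rank the landmarks by their
#' residual error, delete the worst batch from both sides, re-register, and
#' repeat. Landmarks listed in `protected` (e.g. the apex landmark, which
#' anchors the cochlear height) are never deleted — when the worst landmark
#' is protected, the worst *deletable* one goes instead. Batches are
#' truncated so the set never shrinks below `min_landmarks`; pruning stops
#' when the plan is exhausted or the floor is reached.
#'
#' @param model,target Corresponding [landmark_set()]s.
#' @param batch_sizes Integer vector: number of landmarks to delete at each
#'   step (e.g. `c(3, 2, 2, 1, 1, 1, 1, 1)`). An empty plan performs a single
#'   registration with no deletion.
#' @param min_landmarks Minimum landmarks to retain (>= 4, default 4).
#' @param protected Labels (in the *current* numbering at each step of the
#'   original set; see Details) never to delete. Protection is tracked
#'   through renumbering.
#' @param warm_start Start each re-registration from the previous optimum
#'   instead of the identity (default FALSE: restart from identity).
#' @param ... Passed to [register()] (`tol`, `max_iterations`,
#'   `reflection_search`).
#' @details Protected labels refer to the numbering of the input sets;
#'   internally they are followed through the consecutive renumbering that
#'   [delete_landmarks()] applies after each step.
#' @return An object of class `cochlear_case_report`: a list with `steps`
#'   (tibble: `step`, `n_landmarks`, `deleted` original labels, `mae_mm`,
#'   `ssd_mm2`, `iterations`), `fits` (the per-step registration objects),
#'   and `final` (the last fit).
#' @export
prune_landmarks <- function(model, target, batch_sizes = integer(),
                            min_landmarks = 4, protected = integer(),
                            warm_start = FALSE, ...) {
  if (min_landmarks < 4) stop("`min_landmarks` must be >= 4", call. = FALSE)
  protected <- as.integer(protected)
  if (!all(protected %in% model$label)) {
    stop("protected labels must exist in the landmark set", call. = FALSE)
  }
  # original labels tracked alongside the consecutive working labels
  original <- model$label
  cur_m <- model
  cur_t <- target
  steps <- list()
  fits <- list()
  fit <- register(cur_m, cur_t, ...)
  steps[[1]] <- tibble::tibble(
    step = 1L, n_landmarks = nrow(cur_m),
    deleted = list(integer()), mae_mm = fit$mae,
    ssd_mm2 = fit$ssd, iterations = fit$iterations
  )
  fits[[1]] <- fit
  for (batch in batch_sizes) {
    batch <- min(batch, nrow(cur_m) - min_landmarks)
    if (batch <= 0) break
    ranked <- rank_by_error(fit)
    prot_cur <- which(original %in% protected)   # working labels protected
    deletable <- ranked[!ranked %in% prot_cur]
    if (length(deletable) < batch) {
      stop("protected labels leave too few deletable landmarks for the batch",
           call. = FALSE)
    }
    kill <- deletable[seq_len(batch)]
    deleted_orig <- original[kill]
    original <- original[-kill]
    pair <- delete_landmarks(cur_m, cur_t, kill)
    cur_m <- pair$model
    cur_t <- pair$target
    fit <- register(cur_m, cur_t,
                    init = if (warm_start) fit$params else NULL, ...)
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, n_landmarks = nrow(cur_m),
      deleted = list(sort(deleted_orig)), mae_mm = fit$mae,
      ssd_mm2 = fit$ssd, iterations = fit$iterations
    )
    fits[[length(fits) + 1L]] <- fit
  }
  structure(
    list(steps = dplyr::bind_rows(steps), fits = fits, final = fit,
         protected = protected),
    class = "cochlear_case_report"
  )
}

#' @export
print.cochlear_case_report <- function(x, ...) {
  cat("<cochlear_case_report>\n")
  df <- x$steps
  for (i in seq_len(nrow(df))) {
    del <- df$deleted[[i]]
    cat(sprintf("  step %d: %2d landmarks%s, MAE = %.4f mm (%d iterations)\n",
                df$step[i], df$n_landmarks[i],
                if (length(del)) paste0(" (deleted ",
                                        paste(del, collapse = ", "), ")")
                else "",
                df$mae_mm[i], df$iterations[i]))
  }
  if (nrow(df) > 1) {
    cat(sprintf("  overall MAE reduction: %.2f%%\n",
                reduction_percent(df$mae_mm[1], df$mae_mm[nrow(df)])))
  }
  invisible(x)
}

#' @rdname tidy.cochlear_registration
#' @method tidy cochlear_case_report
#' @export
tidy.cochlear_case_report <- function(x, ...) {
  df <- x$steps
  df$deleted <- vapply(df$deleted, function(d) paste(d, collapse = ","), "")
  df$reduction_vs_first_pct <- ifelse(
    df$step == 1L, 0,
    reduction_percent(df$mae_mm[1], df$mae_mm)
  )
  df
}

#' @rdname tidy.cochlear_registration
#' @method glance cochlear_case_report
#' @export
glance.cochlear_case_report <- function(x, ...) {
  df <- x$steps
  tibble::tibble(
    n_steps = nrow(df),
    n_initial = df$n_landmarks[1],
    n_final = df$n_landmarks[nrow(df)],
    mae_initial_mm = df$mae_mm[1],
    mae_final_mm = df$mae_mm[nrow(df)],
    reduction_pct = if (nrow(df) > 1)
      reduction_percent(df$mae_mm[1], df$mae_mm[nrow(df)]) else 0
  )
}

#' Write a pruning case report
#'
#' Writes the report as JSON and, alongside it, a human-readable text table
#' (description, landmark count, MAE in mm).
#'
#' @param report A `cochlear_case_report`.
#' @param path Output JSON file; the text table goes to the same path with
#'   extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "cochlear_case_report"))
  df <- report$steps
  jsonlite::write_json(
    list(
      steps = lapply(seq_len(nrow(df)), function(i) list(
        step = df$step[i],
        n_landmarks = df$n_landmarks[i],
        deleted = df$deleted[[i]],
        mae_mm = df$mae_mm[i],
        ssd_mm2 = df$ssd_mm2[i],
        iterations = df$iterations[i]
      )),
      protected = report$protected,
      overall_reduction_pct = if (nrow(df) > 1)
        reduction_percent(df$mae_mm[1], df$mae_mm[nrow(df)]) else 0
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  txt <- file.path(dirname(path),
                   sub("\\.json$", ".txt", basename(path), ignore.case = TRUE))
  lines <- c(
    sprintf("%-40s %10s %12s", "Description", "Landmarks", "MAE (mm)"),
    vapply(seq_len(nrow(df)), function(i) {
      del <- df$deleted[[i]]
      desc <- if (i == 1) "initial registration"
              else sprintf("deleted landmark(s) %s", paste(del, collapse = ", "))
      sprintf("%-40s %10d %12.4f", desc, df$n_landmarks[i], df$mae_mm[i])
    }, "")
  )
  writeLines(lines, txt)
  invisible(path)
}
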