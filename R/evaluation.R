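#' Relative error and precision of an activation-energy estimate
#'
#' For a true activation energy `E_A` and an estimate with mean `m` and
#' standard error `se`, the relative error and precision (both percent)
#' are
#' \deqn{R = 100\,|m - E_A| / E_A, \qquad P = 100\, se / E_A.}
#' High accuracy and high precision correspond to low `R` and low `P`.
#'
#' @param estimate an [ea_estimate()] or a numeric mean.
#' @param true_ea the activation energy used to generate the data, eV
#'   (> 0).
#' @param se standard error (only when `estimate` is numeric).
#' @return A list with components `R` and `P` (percent).
#' @export
error_metrics <- function(estimate, true_ea, se = NULL) {
  stopifnot(is.numeric(true_ea), true_ea > 0)
  if (inherits(estimate, "ea_estimate")) {
    m <- estimate$mean
    s <- estimate$se
  } else {
    m <- estimate
    s <- se
  }
  list(R = 100 * abs(m - true_ea) / true_ea,
       P = if (is.null(s)) NA_real_ else 100 * s / true_ea)
}

#' Factor grid for a factorial evaluation
#'
#' Builds the design-factor grid crossed in [run_factorial()]. The full
#' study grid is `design_grid()` with all three levels of each factor (81
#' designs); subsets give reduced sweeps.
#'
#' @param fracsamp,timesamp,tempsamp,reps factor levels (see
#'   [design_preset()]).
#' @return A data frame with one row per design cell.
#' @export
design_grid <- function(fracsamp = c(0.001, 0.005, 0.01),
                        timesamp = c(5, 10, 15),
                        tempsamp = c(3, 6, 11),
                        reps = c(1, 3, 5)) {
  expand.grid(fracsamp = fracsamp, timesamp = timesamp,
              tempsamp = tempsamp, reps = reps,
              KEEP.OUT.ATTRS = FALSE)
}

#' Factorial simulation study of estimator error
#'
#' For every (design cell x true activation energy x Monte Carlo replicate)
#' a dataset is simulated with [simulate_design()] and every requested
#' method is run on that same dataset (methods are paired within a
#' dataset, which sharpens method comparisons). Each run is summarised by
#' its relative error and precision ([error_metrics()]). Cell seeds are
#' spawned deterministically from the master seed, and an optional CSV
#' checkpoint lets interrupted sweeps resume.
#'
#' @param methods character vector of method ids (see [method_table()]).
#' @param grid data frame of design cells (see [design_grid()]).
#' @param ea_values true activation energies, eV.
#' @param n_mc Monte Carlo replicates per cell.
#' @param seed master seed.
#' @param model_base baseline [arrhenius_model()] parameters as a list
#'   (`theta01`, `theta02`, `theta03`, `N`); the activation energy is taken
#'   from `ea_values`.
#' @param chain [chain_control()] passed to the MCMC methods.
#' @param checkpoint optional CSV path; completed rows are reloaded and
#'   skipped on re-run.
#' @param verbose print progress?
#' @param ... further arguments passed to [run_method()].
#' @return A data frame with one row per (cell x E_A x MC rep x method):
#'   design factors, `true_ea`, `method`, `seed`, `ea_hat`, `ea_se`, `R`,
#'   `P`, `status`.
#' @export
run_factorial <- function(methods, grid, ea_values, n_mc = 20, seed = 1,
                          model_base = list(theta01 = 1.5, theta02 = 1,
                                            theta03 = 0.5, N = 15000),
                          chain = chain_control(), checkpoint = NULL,
                          verbose = FALSE, ...) {
  stopifnot(length(methods) >= 1, nrow(grid) >= 1, length(ea_values) >= 1,
            n_mc >= 1)
  cells <- expand.grid(cell = seq_len(nrow(grid)),
                       ea = ea_values, mc = seq_len(n_mc),
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(as.integer(seed))
  cells$seed <- sample.int(.Machine$integer.max, nrow(cells))

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.csv(checkpoint)
  }
  key_of <- function(cell, ea, mc, method) {
    paste(cell, ea, mc, method, sep = "|")
  }
  done_keys <- if (!is.null(done)) {
    key_of(done$cell, done$true_ea, done$mc, done$method)
  } else character(0)

  rows <- if (!is.null(done)) split(done, seq_len(nrow(done))) else list()
  for (i in seq_len(nrow(cells))) {
    ci <- cells$cell[i]
    g <- grid[ci, ]
    ea <- cells$ea[i]
    mc <- cells$mc[i]
    todo <- methods[!(key_of(ci, ea, mc, methods) %in% done_keys)]
    if (!length(todo)) next
    model <- arrhenius_model(model_base$theta01, model_base$theta02,
                             model_base$theta03, e_a = ea,
                             N = model_base$N)
    design <- design_preset(tempsamp = g$tempsamp, reps = g$reps,
                            timesamp = g$timesamp, fracsamp = g$fracsamp)
    ds <- simulate_design(model, design, seed = cells$seed[i])
    for (m in todo) {
      set.seed((cells$seed[i] + match(m, method_table()$method)) %%
                 .Machine$integer.max)
      est <- tryCatch(
        suppressWarnings(run_method(m, ds, chain = chain, ...)),
        error = function(e) e
      )
      if (inherits(est, "error")) {
        rec <- data.frame(cell = ci, fracsamp = g$fracsamp,
                          timesamp = g$timesamp, tempsamp = g$tempsamp,
                          reps = g$reps, true_ea = ea, mc = mc,
                          method = m, seed = cells$seed[i],
                          ea_hat = NA_real_, ea_se = NA_real_,
                          R = NA_real_, P = NA_real_,
                          status = paste("failed:",
                                         conditionMessage(est)))
      } else {
        err <- error_metrics(est, ea)
        rec <- data.frame(cell = ci, fracsamp = g$fracsamp,
                          timesamp = g$timesamp, tempsamp = g$tempsamp,
                          reps = g$reps, true_ea = ea, mc = mc,
                          method = m, seed = cells$seed[i],
                          ea_hat = est$mean, ea_se = est$se,
                          R = err$R, P = err$P, status = "ok")
      }
      rows[[length(rows) + 1L]] <- rec
      if (!is.null(checkpoint)) {
        out <- do.call(rbind, rows)
        write.csv(out, checkpoint, row.names = FALSE)
      }
    }
    if (verbose) {
      message(sprintf("cell %d/%d (E_A=%.2f, mc %d) done",
                      ci, nrow(grid), ea, mc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression-tree analysis of estimation-error drivers
#'
#' Fits a greedy binary regression tree (recursive partitioning, anova
#' method: each split minimises the within-node sum of squared errors) of
#' the absolute relative error on the four design factors. Splits are
#' accepted only if they reduce the node SSE by at least `cp` times the
#' root SSE, and nodes smaller than `minbucket` are not created — the
#' standard complexity/stopping rules of the CART methodology. Leaf values
#' are mean percent errors.
#'
#' @param records evaluation records from [run_factorial()] (rows with
#'   `status != "ok"` are dropped).
#' @param response response column name (default the relative error `"R"`).
#' @param predictors design-factor column names.
#' @param cp complexity parameter: minimum relative SSE improvement.
#' @param minbucket minimum records per leaf.
#' @return An object of class `ea_error_tree` wrapping the `rpart` fit,
#'   with the nested node structure in `$tree` and the first split
#'   variable in `$first_split` (`NA` for a root-only tree).
#' @export
cart_error_tree <- function(records, response = "R",
                            predictors = c("fracsamp", "timesamp",
                                           "tempsamp", "reps"),
                            cp = 0.01, minbucket = 5) {
  stopifnot(is.data.frame(records), response %in% names(records),
            all(predictors %in% names(records)))
  d <- records[records$status == "ok" & is.finite(records[[response]]),
               c(response, predictors)]
  if (nrow(d) < 20) stop("need at least 20 usable records")
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = " + ")))
  fit <- rpart::rpart(form, data = d, method = "anova",
                      control = rpart::rpart.control(
                        cp = cp, minbucket = minbucket,
                        minsplit = 2 * minbucket, xval = 0))
  frame <- fit$frame
  first_split <- if (nrow(frame) > 1) as.character(frame$var[1]) else NA
  structure(list(rpart = fit, tree = rpart_to_list(fit),
                 first_split = first_split, n = nrow(d)),
            class = "ea_error_tree")
}

# Convert an rpart anova fit into a nested list (split variable, threshold,
# node mean, node size) mirroring the tree structure.
rpart_to_list <- function(fit) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  splits <- fit$splits
  split_row <- 0L
  build <- function(id) {
    i <- match(id, ids)
    node <- list(n = frame$n[i], mean = frame$yval[i])
    if (as.character(frame$var[i]) != "<leaf>") {
      split_row <<- split_row + 1L
      node$var <- as.character(frame$var[i])
      node$threshold <- unname(splits[split_row, "index"])
      # rpart orders children by the split sign; ncat = -1 means "<" goes left
      node$left <- build(2L * id)
      node$right <- build(2L * id + 1L)
    }
    node
  }
  build(1L)
}

#' @export
print.ea_error_tree <- function(x, digits = 3, ...) {
  cat("<ea_error_tree> n =", x$n, "records; first split:",
      if (is.na(x$first_split)) "none (single leaf)" else x$first_split,
      "\n")
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$var)) {
      cat(pad, "* leaf: mean ", signif(node$mean, digits), "% (n=",
          node$n, ")\n", sep = "")
    } else {
      cat(pad, node$var, " < ", signif(node$threshold, digits),
          "  [mean ", signif(node$mean, digits), "%, n=", node$n, "]\n",
          sep = "")
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  rec(x$tree, 0)
  invisible(x)
}
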