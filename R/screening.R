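#' Pearson correlation matrix over grid cells
#'
#' Correlations are computed across all mutually valid grid cells (the
#' shared stack mask), not only at occurrence points, so the matrix is
#' independent of the presence data.
#'
#' @param stack A [layer_stack()].
#' @param vars Variables to include (default all).
#' @return Square symmetric correlation matrix; entries involving a
#'   zero-variance layer are `NA`.
#' @export
correlation_matrix <- function(stack, vars = layer_names(stack)) {
  valid <- stack$mask
  x <- sapply(vars, function(v) stack$layers[[v]][valid])
  suppressWarnings(stats::cor(x, method = "pearson"))
}

#' Two-stage environmental variable screening
#'
#' Stage 1 drops variables whose percent contribution is below `c_min`
#' (percentage points). Stage 2 visits the survivors in decreasing
#' contribution (ties broken alphabetically) and keeps a variable only if
#' its absolute Pearson correlation with every already-kept variable is
#' below `r_max` — of any collinear pair, the higher-contribution member
#' is preserved. Zero-variance layers have undefined correlations and are
#' dropped with a warning.
#'
#' @param stack A [layer_stack()] containing the candidate variables.
#' @param contributions Named numeric vector of percent contributions
#'   (summing to 100 within tolerance), e.g. from
#'   [percent_contribution()] of an initial all-variable model.
#' @param c_min Minimum percent contribution retained (default 0.1).
#' @param r_max Collinearity threshold on |r| (default 0.8).
#' @return A `variable_selection` list with elements `kept` (ordered
#'   character vector), `dropped` (data.frame of variable, reason),
#'   `contributions`, and `correlation` (the matrix used).
#' @export
select_variables <- function(stack, contributions, c_min = 0.1, r_max = 0.8) {
  vars <- names(contributions)
  if (is.null(vars) || !all(vars %in% layer_names(stack))) {
    stop("`contributions` must be named after layers in `stack`")
  }
  if (length(vars) < 2) stop("need at least 2 variables to screen")
  if (abs(sum(contributions) - 100) > 1e-6 && sum(contributions) != 0) {
    stop("contributions must sum to 100")
  }

  dropped <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note_drop <- function(v, reason) {
    dropped <<- rbind(dropped, data.frame(variable = v, reason = reason,
                                          stringsAsFactors = FALSE))
  }

  # stage 1: contribution filter
  low <- vars[contributions < c_min]
  for (v in low) note_drop(v, "low-contribution")
  survivors <- setdiff(vars, low)

  cmat <- correlation_matrix(stack, vars)
  constant <- survivors[vapply(survivors, function(v)
    stats::sd(stack$layers[[v]][stack$mask]) == 0, logical(1))]
  if (length(constant)) {
    warning("zero-variance layer(s) dropped: ", paste(constant, collapse = ", "))
    for (v in constant) note_drop(v, "zero-variance")
    survivors <- setdiff(survivors, constant)
  }

  # stage 2: greedy collinearity resolution, highest contribution first
  ord <- survivors[order(-contributions[survivors], survivors)]
  kept <- character(0)
  for (v in ord) {
    r <- abs(cmat[v, kept])
    if (length(kept) == 0 || all(r < r_max, na.rm = TRUE)) {
      kept <- c(kept, v)
    } else {
      partner <- kept[which(r >= r_max)[1]]
      note_drop(v, paste0("collinear-with-", partner))
    }
  }

  structure(
    list(kept = kept, dropped = dropped,
         contributions = contributions, correlation = cmat,
         c_min = c_min, r_max = r_max),
    class = "variable_selection"
  )
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("<variable_selection> kept %d of %d variables (c_min=%g, r_max=%g)\n",
              length(x$kept), length(x$contributions), x$c_min, x$r_max))
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("    %s (%s)\n", x$dropped$variable[i], x$dropped$reason[i]))
    }
  }
  invisible(x)
}

#' Write a variable selection to CSV
#'
#' @param sel A `variable_selection`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_selection <- function(sel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    variable = names(sel$contributions),
    contribution_pct = as.numeric(sel$contributions),
    status = ifelse(names(sel$contributions) %in% sel$kept, "kept", "dropped"),
    stringsAsFactors = FALSE
  )
  tab <- merge(tab, sel$dropped, by = "variable", all.x = TRUE)
  p1 <- file.path(dir, "variable_selection.csv")
  p2 <- file.path(dir, "correlation_matrix.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  utils::write.csv(as.data.frame(sel$correlation), p2, row.names = TRUE)
  invisible(c(p1, p2))
}
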