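FEATURE_CLASSES <- c(L = "linear", Q = "quadratic", P = "product",
                     T = "threshold", H = "hinge")

#' Parse a feature-combination code
#'
#' @param fc A string such as `"LQH"` (any subset of L, Q, P, T, H) or a
#'   character vector of single letters.
#' @return Character vector of class letters, in canonical L,Q,P,T,H order.
#' @export
parse_fc <- function(fc) {
  letters <- if (length(fc) == 1) strsplit(toupper(fc), "")[[1]] else toupper(fc)
  bad <- setdiff(letters, names(FEATURE_CLASSES))
  if (length(bad)) stop("unknown feature class letters: ", paste(bad, collapse = ""))
  if (length(letters) == 0) stop("empty feature combination")
  names(FEATURE_CLASSES)[names(FEATURE_CLASSES) %in% letters]
}

# Coerce a layer_stack (valid cells) or matrix to a named value matrix.
as_value_matrix <- function(x, vars = NULL) {
  if (inherits(x, "layer_stack")) {
    vars <- vars %||% layer_names(x)
    valid <- x$mask
    m <- sapply(vars, function(v) x$layers[[v]][valid])
    if (is.null(dim(m))) m <- matrix(m, ncol = length(vars), dimnames = list(NULL, vars))
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(colnames(m))) stop("value matrix must have variable column names")
  if (!is.null(vars)) m <- m[, vars, drop = FALSE]
  m
}

#' Build MaxEnt feature definitions
#'
#' Constructs the feature set for the requested classes from background
#' variable values. Every variable is first rescaled to \[0,1\] using its
#' background minimum/maximum (values outside the range are clamped at
#' evaluation time). Classes: linear (the rescaled value), quadratic (its
#' square), product (pairwise products of distinct variables), threshold
#' (step indicators at `n_knots` evenly spaced interior knots) and hinge
#' (forward and reverse hinges at the same knots).
#'
#' @param bg Background variable values: a matrix with named columns or a
#'   [layer_stack()] (valid cells are used).
#' @param classes Feature classes, e.g. `"LQH"` or `c("L","Q")`.
#' @param n_knots Knots per variable for threshold/hinge features
#'   (default 30); knots lie strictly inside the rescaled range.
#' @return A `feature_spec` data.frame (name, class, var1, var2, knot,
#'   orientation) with the per-variable rescaling ranges as attribute
#'   `ranges`.
#' @export
build_features <- function(bg, classes = "LQ", n_knots = 30) {
  X <- as_value_matrix(bg)
  classes <- parse_fc(classes)
  vars <- colnames(X)
  ranges <- lapply(vars, function(v) {
    r <- range(X[, v], finite = TRUE)
    c(min = r[1], max = r[2])
  })
  names(ranges) <- vars

  rows <- list()
  add <- function(name, class, var1, var2 = NA_character_,
                  knot = NA_real_, orientation = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, class = class, var1 = var1, var2 = var2,
      knot = knot, orientation = orientation, stringsAsFactors = FALSE)
  }
  knots <- seq_len(n_knots) / (n_knots + 1)
  for (cl in classes) {
    if (cl == "L") for (v in vars) add(v, "linear", v)
    if (cl == "Q") for (v in vars) add(paste0(v, "^2"), "quadratic", v)
    if (cl == "P") {
      if (length(vars) < 2) {
        message("product features requested with a single variable; none built")
      } else {
        pairs <- utils::combn(vars, 2)
        for (i in seq_len(ncol(pairs))) {
          add(paste0(pairs[1, i], "*", pairs[2, i]), "product",
              pairs[1, i], pairs[2, i])
        }
      }
    }
    if (cl == "T") for (v in vars) for (k in knots) {
      add(sprintf("(%s>=%.6g)", v, k), "threshold", v, knot = k)
    }
    if (cl == "H") for (v in vars) for (k in knots) {
      add(sprintf("h(%s|%.6g)", v, k), "hinge", v, knot = k, orientation = "forward")
      add(sprintf("h'(%s|%.6g)", v, k), "hinge", v, knot = k, orientation = "reverse")
    }
  }
  spec <- do.call(rbind, rows)
  structure(spec, ranges = ranges, classes = classes,
            class = c("feature_spec", "data.frame"))
}

# Rescale raw variable values to [0,1] with clamping.
rescale01 <- function(x, rng) {
  span <- rng["max"] - rng["min"]
  if (span <= 0) return(rep(0, length(x)))
  pmin(1, pmax(0, (x - rng["min"]) / span))
}

#' Evaluate features on raw variable values
#'
#' @param features A `feature_spec` from [build_features()].
#' @param X Matrix of raw variable values (rows = points, named columns)
#'   or a [layer_stack()].
#' @return Numeric matrix (points x features), all values in \[0,1\].
#' @export
evaluate_features <- function(features, X) {
  X <- as_value_matrix(X)
  vars <- unique(c(features$var1, stats::na.omit(features$var2)))
  missing <- setdiff(vars, colnames(X))
  if (length(missing)) stop("variables missing from data: ", paste(missing, collapse = ", "))
  ranges <- attr(features, "ranges")
  Z <- sapply(vars, function(v) rescale01(X[, v], ranges[[v]]))
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = length(vars), dimnames = list(NULL, vars))
  if (any(!is.finite(Z))) {
    bad <- vars[apply(Z, 2, function(z) any(!is.finite(z)))]
    stop("non-finite values in variable(s): ", paste(bad, collapse = ", "))
  }
  out <- matrix(0, nrow(Z), nrow(features),
                dimnames = list(NULL, features$name))
  for (i in seq_len(nrow(features))) {
    z <- Z[, features$var1[i]]
    out[, i] <- switch(features$class[i],
      linear = z,
      quadratic = z^2,
      product = z * Z[, features$var2[i]],
      threshold = as.numeric(z >= features$knot[i]),
      hinge = if (features$orientation[i] == "forward") {
        pmax(0, (z - features$knot[i]) / (1 - features$knot[i]))
      } else {
        pmax(0, (features$knot[i] - z) / features$knot[i])
      })
  }
  out
}

# Published MaxEnt default per-class regularization values, interpolated
# on presence sample size m.
beta_class_value <- function(class, m) {
  lqp <- stats::approx(x = c(0, 10, 17, 30, 100),
                       y = c(1, 1, 0.6, 0.5, 0.05), xout = m, rule = 2)$y
  switch(class,
         linear = lqp, quadratic = lqp, product = lqp,
         threshold = 1.0,
         hinge = 0.5,
         stop("unknown feature class: ", class))
}
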