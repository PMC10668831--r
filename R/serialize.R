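#' Serialize a fitted model to plain text
#'
#' Writes a documented key-value header plus a tab-separated coefficient
#' table (feature name, class, variables, knot, orientation, lambda,
#' beta) and the per-variable rescaling ranges. All numbers use 17
#' significant digits so the round trip through [read_maxent_model()] is
#' exact.
#'
#' @param model A `maxent_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_maxent_model <- function(model, path) {
  g <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# nichemax maxent model v1",
    paste("rm", g(model$rm)),
    paste("m", model$m),
    paste("n_bg", model$n_bg),
    paste("n_support", model$n_support),
    paste("logZ", g(model$logZ)),
    paste("entropy", g(model$entropy)),
    paste("gain", g(model$gain)),
    paste("objective", g(model$objective)),
    paste("transform", model$transform),
    paste("classes", paste(attr(model$features, "classes"), collapse = "")),
    paste("vars", paste(model$vars, collapse = ",")),
    "ranges:"
  )
  ranges <- attr(model$features, "ranges")
  for (v in names(ranges)) {
    lines <- c(lines, paste(v, g(ranges[[v]]["min"]), g(ranges[[v]]["max"]), sep = "\t"))
  }
  lines <- c(lines, "features:",
             paste("name", "class", "var1", "var2", "knot", "orientation",
                   "lambda", "beta", sep = "\t"))
  f <- model$features
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, paste(
      f$name[i], f$class[i], f$var1[i],
      ifelse(is.na(f$var2[i]), ".", f$var2[i]),
      ifelse(is.na(f$knot[i]), ".", g(f$knot[i])),
      ifelse(is.na(f$orientation[i]), ".", f$orientation[i]),
      g(model$lambda[i]), g(model$beta[i]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path File written by [write_maxent_model()].
#' @return A `maxent_model` usable with [predict.maxent_model()] (the
#'   fitting trace is not preserved).
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path)
  if (!grepl("nichemax maxent model", lines[1])) stop("not a nichemax model file")
  ri <- which(lines == "ranges:")
  fi <- which(lines == "features:")
  kv <- strsplit(lines[2:(ri - 1)], " ")
  hdr <- stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = " ")),
                         vapply(kv, `[[`, character(1), 1))
  ranges <- list()
  for (ln in lines[(ri + 1):(fi - 1)]) {
    p <- strsplit(ln, "\t")[[1]]
    ranges[[p[1]]] <- c(min = as.numeric(p[2]), max = as.numeric(p[3]))
  }
  tab <- utils::read.delim(text = paste(lines[(fi + 1):length(lines)], collapse = "\n"),
                           stringsAsFactors = FALSE, na.strings = ".")
  features <- tab[c("name", "class", "var1", "var2", "knot", "orientation")]
  features$var2 <- as.character(features$var2)
  features$orientation <- as.character(features$orientation)
  attr(features, "ranges") <- ranges
  attr(features, "classes") <- parse_fc(hdr$classes)
  class(features) <- c("feature_spec", "data.frame")
  structure(
    list(
      features = features,
      lambda = tab$lambda, beta = tab$beta,
      rm = as.numeric(hdr$rm), vars = strsplit(hdr$vars, ",")[[1]],
      m = as.integer(hdr$m), n_bg = as.integer(hdr$n_bg),
      n_support = as.integer(hdr$n_support),
      logZ = as.numeric(hdr$logZ), entropy = as.numeric(hdr$entropy),
      gain = as.numeric(hdr$gain), objective = as.numeric(hdr$objective),
      transform = hdr$transform,
      converged = NA, sweeps = NA_integer_, trace = NULL
    ),
    class = "maxent_model"
  )
}
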