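# Regression-tree (CART) subgroup discovery on ln titers.
#
# Standard binary recursive partitioning minimizing within-node sum of
# squared errors. At each node, every predictor is scanned over candidate
# thresholds placed at midpoints of adjacent sorted unique values; the split
# maximizing the SSE reduction wins, subject to min_split / min_bucket /
# cost-complexity (reduction >= cp * root SSE) / depth constraints. Ties are
# broken deterministically: earlier predictor in `predictors` first, then the
# smaller threshold. Growth is depth-limited to 3 split levels so trees stay
# interpretable, mirroring the analysis design.

#' Best SSE-reducing split of one node
#'
#' Scans all predictors and candidate midpoints using cumulative sums, so one
#' node costs O(n log n).
#' @return `NULL` when no admissible split exists, else a list with
#'   `var`, `threshold`, `reduction`, `n_left`, `n_right`.
#' @noRd
best_split <- function(data, response, predictors, min_bucket) {
  y <- data[[response]]
  n <- length(y)
  sse_parent <- sum((y - mean(y))^2)
  best <- NULL
  for (v in predictors) {
    x <- data[[v]]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    # candidate boundaries after position i where xs[i] < xs[i+1]
    cut_at <- which(diff(xs) > 0)
    cut_at <- cut_at[cut_at >= min_bucket & (n - cut_at) >= min_bucket]
    if (!length(cut_at)) next
    sse_l <- cs2[cut_at] - cs[cut_at]^2 / cut_at
    sse_r <- (tot2 - cs2[cut_at]) - (tot - cs[cut_at])^2 / (n - cut_at)
    red <- sse_parent - (sse_l + sse_r)
    i <- which.max(red)             # first max: smaller threshold on ties
    if (red[i] <= 0) next
    thr <- (xs[cut_at[i]] + xs[cut_at[i] + 1]) / 2
    if (is.null(best) || red[i] > best$reduction + 1e-10) {
      best <- list(var = v, threshold = thr, reduction = red[i],
                   n_left = cut_at[i], n_right = n - cut_at[i])
    }
  }
  best
}

grow_node <- function(data, response, predictors, depth, params, root_sse) {
  y <- data[[response]]
  node <- list(n = length(y), mean = mean(y), sse = sum((y - mean(y))^2),
               depth = depth)
  if (depth >= params$max_depth || length(y) < params$min_split ||
      node$sse <= 0) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- best_split(data, response, predictors, params$min_bucket)
  if (is.null(sp) || sp$reduction < params$cp * root_sse) {
    node$leaf <- TRUE
    return(node)
  }
  left <- data[[sp$var]] <= sp$threshold
  node$leaf <- FALSE
  node$split_var <- sp$var
  node$threshold <- sp$threshold
  node$reduction <- sp$reduction
  node$left <- grow_node(data[left, , drop = FALSE], response, predictors,
                         depth + 1L, params, root_sse)
  node$right <- grow_node(data[!left, , drop = FALSE], response, predictors,
                          depth + 1L, params, root_sse)
  node
}

#' Fit a depth-limited regression tree of ln titer on age and sampling hour
#'
#' @param cohort a `cohort_table` (or plain data frame).
#' @param analyte analyte whose records are modeled; `NULL` uses all rows
#'   (for data frames without an analyte column).
#' @param response response column; the default `"ln_titer"` is derived as
#'   `log(titer)` when absent.
#' @param predictors predictor columns, scanned in order (order breaks ties).
#' @param min_split minimum node size to attempt a split (default 20).
#' @param min_bucket minimum child size (default 7).
#' @param cp complexity parameter: a split must reduce SSE by at least
#'   `cp * root SSE` (default 0.01).
#' @param max_depth maximum number of split levels on any path (default 3).
#' @return object of class `cart_tree` (nested node list plus parameters).
#'   A constant response or constant predictors give a root-only tree.
#' @export
fit_cart <- function(cohort, analyte = NULL, response = "ln_titer",
                     predictors = c("age_years", "tod_hour"),
                     min_split = 20L, min_bucket = 7L, cp = 0.01,
                     max_depth = 3L) {
  df <- as.data.frame(cohort)
  if (!is.null(analyte)) {
    df <- df[df$analyte == analyte, , drop = FALSE]
    if (!nrow(df)) stop_data(sprintf("analyte not present: %s", analyte))
  }
  if (!response %in% names(df)) {
    if (response == "ln_titer" && "titer" %in% names(df)) {
      if (any(df$titer <= 0)) stop_value("nonpositive titers cannot be log-transformed")
      df$ln_titer <- log(df$titer)
    } else {
      stop_data(sprintf("response column not found: %s", response))
    }
  }
  missing_p <- setdiff(predictors, names(df))
  if (length(missing_p)) {
    stop_data(sprintf("predictor column(s) not found: %s",
                      paste(missing_p, collapse = ", ")))
  }
  if (nrow(df) < min_split) {
    stop_data(sprintf("need at least min_split = %d records", min_split))
  }
  params <- list(min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket),
                 cp = cp, max_depth = as.integer(max_depth))
  y <- df[[response]]
  root_sse <- sum((y - mean(y))^2)
  root <- grow_node(df[c(response, predictors)], response, predictors,
                    0L, params, root_sse)
  structure(list(root = root, response = response, predictors = predictors,
                 params = params, n = nrow(df), analyte = analyte),
            class = "cart_tree")
}

#' Predict node means from a fitted tree
#' @param object a `cart_tree`.
#' @param newdata data frame with the predictor columns.
#' @param ... unused.
#' @return numeric vector of leaf means.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$split_var]] <= node$threshold) node$left else node$right
    }
    node$mean
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$root, newdata[i, ]), 0)
}

#' Enumerate a tree's internal splits with their ancestor constraints
#'
#' Each row describes one internal node: the split variable and threshold
#' plus the age interval `(age_lo, age_hi]`-style bounds accumulated along
#' the path (open bounds are -Inf/Inf), and the node's depth and size.
#' @param tree a `cart_tree`.
#' @return data frame, one row per internal node (0 rows for a root-only
#'   tree), ordered by depth then threshold.
#' @export
cart_splits <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  acc <- list()
  walk <- function(node, bounds) {
    if (node$leaf) return(invisible())
    acc[[length(acc) + 1L]] <<- data.frame(
      var = node$split_var, threshold = node$threshold, depth = node$depth,
      n = node$n, reduction = node$reduction,
      age_lo = bounds$age_lo, age_hi = bounds$age_hi,
      tod_lo = bounds$tod_lo, tod_hi = bounds$tod_hi,
      stringsAsFactors = FALSE)
    bl <- br <- bounds
    if (node$split_var == "age_years") {
      bl$age_hi <- min(bl$age_hi, node$threshold)
      br$age_lo <- max(br$age_lo, node$threshold)
    } else if (node$split_var == "tod_hour") {
      bl$tod_hi <- min(bl$tod_hi, node$threshold)
      br$tod_lo <- max(br$tod_lo, node$threshold)
    }
    walk(node$left, bl)
    walk(node$right, br)
  }
  walk(tree$root, list(age_lo = -Inf, age_hi = Inf, tod_lo = -Inf, tod_hi = Inf))
  if (!length(acc)) {
    return(data.frame(var = character(), threshold = numeric(),
                      depth = integer(), n = integer(), reduction = numeric(),
                      age_lo = numeric(), age_hi = numeric(),
                      tod_lo = numeric(), tod_hi = numeric()))
  }
  out <- do.call(rbind, acc)
  out[order(out$depth, out$threshold), , drop = FALSE]
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> %s ~ %s, n = %d (min_split %d, min_bucket %d, cp %g, depth <= %d)\n",
              x$response, paste(x$predictors, collapse = " + "), x$n,
              x$params$min_split, x$params$min_bucket, x$params$cp,
              x$params$max_depth))
  rec <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s%s leaf: n=%d mean=%.4f\n", pad, label, node$n, node$mean))
    } else {
      cat(sprintf("%s%s %s <= %.6g  (n=%d, mean=%.4f)\n", pad, label,
                  node$split_var, node$threshold, node$n, node$mean))
      rec(node$left, indent + 1L, "<=")
      rec(node$right, indent + 1L, ">")
    }
  }
  rec(x$root, 0L, "root:")
  invisible(x)
}
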