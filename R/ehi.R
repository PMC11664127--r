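# EHI assembly: transformation risk from overlaps, the core index
# EHI = B * (1 - P * T), and natural-breaks classification.

#' Transformation risk for an ecotone in a region
#'
#' Collapses the ecotone's pairwise Sorensen overlaps in the continent's
#' matrix to a scalar T (default rule: max over the pairs, the conservative
#' worst-case transformation pressure; "mean" and "sum_capped" — the sum of
#' pair overlaps capped at 1 — are available).  Every pixel of one ecotone
#' on one continent shares the same T (the uniform transformation-risk
#' standard).  When the continent has no usable overlaps for the ecotone,
#' falls back to the worldwide matrix; with no data at either level T is
#' no-data (NA).
#'
#' @param continental `bce_overlap_set` with `grouping = "continent"` (may
#'   be NULL).
#' @param ecotone ecotone label.
#' @param continent continent label.
#' @param rule "max", "mean" or "sum_capped".
#' @param worldwide optional fallback `bce_overlap_set`.
#' @return list with `value` (T in \[0,1\] or NA), `source_region`, `rule`.
#' @export
assign_transformation_risk <- function(continental, ecotone, continent,
                                       rule = c("max", "mean", "sum_capped"),
                                       worldwide = NULL) {
  rule <- match.arg(rule)
  collapse <- function(x) switch(rule,
    max = max(x), mean = mean(x), sum_capped = min(sum(x), 1))
  pick <- function(oset, region) {
    m <- oset$matrices[[region]]
    if (is.null(m) || !(ecotone %in% rownames(m))) return(NULL)
    x <- m[ecotone, setdiff(colnames(m), ecotone)]
    x <- x[!is.na(x)]
    if (length(x) == 0L) NULL else x
  }
  x <- if (!is.null(continental)) pick(continental, continent) else NULL
  region <- continent
  if (is.null(x) && !is.null(worldwide)) {
    x <- pick(worldwide, names(worldwide$matrices)[1])
    region <- "worldwide"
  }
  if (is.null(x))
    return(list(value = NA_real_, source_region = NA_character_, rule = rule))
  list(value = collapse(x), source_region = region, rule = rule)
}

#' Ecosystem Health Index
#'
#' `EHI = B * (1 - P * T)`: benefits are discounted by the product of
#' pressure and transformation risk (multiplicative because pressure acting
#' on a transformable system cascades).  Inputs must be in \[0,1\] or NA;
#' NA (no-data) propagates.
#'
#' @param b,p,t numeric vectors in \[0,1\] (recycled to common length).
#' @return numeric vector of EHI in \[0,1\].
#' @export
compute_ehi <- function(b, p, t) {
  for (nm in c("b", "p", "t")) {
    v <- get(nm)
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(sprintf("`%s` outside [0, 1]", nm), call. = FALSE)
  }
  b * (1 - p * t)
}

# Exact Fisher-Jenks dynamic program.  ssd(i, j) of the sorted values is
# O(1) via prefix sums; the DP is O(k n^2) with ties broken toward the
# smallest break index (hence the lower break value).
jenks_dp <- function(x_sorted, k) {
  n <- length(x_sorted)
  cs <- cumsum(x_sorted)
  cs2 <- cumsum(x_sorted^2)
  ssd <- function(i, j) {
    # within-class sum of squared deviations of x_sorted[i..j], vectorized in i
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  cost <- ssd(rep(1L, n), 1:n)  # cost[j] = 1-class cost of x[1..j]
  back <- matrix(0L, k, n)
  for (cls in 2:k) {
    new_cost <- rep(Inf, n)
    for (j in cls:n) {
      i <- cls:j  # first index of the last class
      tot <- cost[i - 1L] + ssd(i, j)
      best <- which.min(tot)  # ties -> smallest i -> lower break value
      new_cost[j] <- tot[best]
      back[cls, j] <- i[best]
    }
    cost <- new_cost
  }
  # recover class boundaries (index of last element of each class)
  bounds <- integer(k)
  j <- n
  for (cls in k:2) {
    bounds[cls] <- j
    j <- back[cls, j] - 1L
  }
  bounds[1] <- j
  list(ssd = cost[n], last_index = bounds)
}

#' Jenks natural breaks
#'
#' Exact minimization of the total within-class sum of squared deviations
#' over all partitions of the sorted values into `k` contiguous classes
#' (Fisher's dynamic program).  Break values are the class maxima of the
#' lower k-1 classes; a value exactly at a break belongs to the lower class.
#'
#' @param values numeric vector (NAs dropped) with at least `k` distinct
#'   finite values.
#' @param k number of classes (default 3: Low / Medium / High).
#' @return object of class `bce_class_breaks`: list with `breaks`
#'   (increasing length k-1; for k = 3 named low_upper, medium_upper),
#'   `k`, `ssd`, `method = "jenks"`, `n`.
#' @export
jenks_breaks <- function(values, k = 3L) {
  x <- values[is.finite(values)]
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (length(unique(x)) < k)
    stop(sprintf("need at least %d distinct finite values, got %d", k,
                 length(unique(x))), call. = FALSE)
  xs <- sort(x)
  if (k == 1L) {
    res <- list(ssd = sum((xs - mean(xs))^2), last_index = length(xs))
  } else {
    res <- jenks_dp(xs, k)
  }
  brk <- if (k > 1) xs[res$last_index[-k]] else numeric(0)
  if (k == 3L) names(brk) <- c("low_upper", "medium_upper")
  structure(list(breaks = brk, k = as.integer(k), ssd = res$ssd,
                 method = "jenks", n = length(xs)),
            class = "bce_class_breaks")
}

#' @export
print.bce_class_breaks <- function(x, ...) {
  cat(sprintf("Jenks natural breaks (k = %d, n = %d, within-class SSD %.4g)\n",
              x$k, x$n, x$ssd))
  if (length(x$breaks))
    cat("  breaks:", paste(signif(x$breaks, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-pixel coastal wetland EHI across co-occurring ecotones
#'
#' Sums EHI over the ecotones sharing a pixel (identified by its cell
#' center).  The result ranges over \[0, n_ecotones\] and is deliberately
#' NOT renormalized: it is a cumulative-benefit summary, not a probability.
#'
#' @param records data.frame with latitude, longitude, ecotone, ehi.
#' @return data.frame with latitude, longitude, n_ecotones, wetland_ehi
#'   (NA when every co-occurring EHI is missing).
#' @export
wetland_ehi_sum <- function(records) {
  key <- paste(records$latitude, records$longitude, sep = "/")
  agg <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    e <- records$ehi[idx]
    data.frame(latitude = records$latitude[idx[1]],
               longitude = records$longitude[idx[1]],
               n_ecotones = length(idx),
               wetland_ehi = if (all(is.na(e))) NA_real_
                             else sum(e, na.rm = TRUE))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$latitude, out$longitude), , drop = FALSE]
}

#' Classify EHI records and summarize class proportions
#'
#' Assigns each record Low / Medium / High using per-ecotone Jenks breaks
#' (value <= low_upper is Low, <= medium_upper is Medium, else High; values
#' exactly at a break go to the lower class).  Records with missing EHI are
#' NoData.  The summary reports proportions over ALL records of each
#' ecotone, with NoData as its own share, so rows sum to 100%.
#'
#' @param records data.frame with `ecotone` and `ehi` columns.
#' @param breaks named list of `bce_class_breaks`, one per ecotone present.
#' @return list with `records` (plus `ehi_class` factor) and `summary`
#'   (data.frame: ecotone, high, medium, low, no_data proportions, n).
#' @export
classify_ehi <- function(records, breaks) {
  lv <- c("High", "Medium", "Low", "NoData")
  cls <- factor(rep(NA_character_, nrow(records)), levels = lv)
  for (eco in unique(records$ecotone)) {
    idx <- which(records$ecotone == eco)
    e <- records$ehi[idx]
    miss <- is.na(e)
    if (all(miss)) {
      cls[idx] <- "NoData"
      next
    }
    bk <- breaks[[eco]]
    if (is.null(bk))
      stop(sprintf("no fitted breaks for ecotone '%s'", eco), call. = FALSE)
    b <- bk$breaks
    lab <- ifelse(e <= b[1], "Low", ifelse(e <= b[2], "Medium", "High"))
    lab[miss] <- "NoData"
    cls[idx] <- lab
  }
  records$ehi_class <- cls
  summ <- do.call(rbind, lapply(split(cls, records$ecotone), function(s) {
    p <- as.numeric(table(s)) / length(s)
    data.frame(high = p[1], medium = p[2], low = p[3], no_data = p[4],
               n = length(s))
  }))
  summ <- cbind(ecotone = rownames(summ), summ)
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}
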