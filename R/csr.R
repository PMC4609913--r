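#' Construct a FRET substrate panel
#'
#' Multiplexed live-cell protease-activity data: fluorescence of a panel
#' of FRET-quenched polypeptide substrates recorded over a handful of
#' time points, per treatment condition and replicate. Cleavage
#' dequenches the substrate, so protease activity appears as the rate of
#' fluorescence increase.
#'
#' @param fluorescence 4-way array \[condition, substrate, replicate,
#'   time\] with dimnames on conditions and substrates.
#' @param timepoints time values (minutes), strictly increasing, >= 2.
#' @return `fret_panel` object.
#' @export
fret_panel <- function(fluorescence, timepoints) {
  if (!is.array(fluorescence) || length(dim(fluorescence)) != 4L)
    stop("fluorescence must be a 4-way array ",
         "[condition, substrate, replicate, time]", call. = FALSE)
  if (length(timepoints) != dim(fluorescence)[4])
    stop("timepoints length must match the 4th array dimension",
         call. = FALSE)
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0))
    stop("need >= 2 strictly increasing timepoints", call. = FALSE)
  all_missing <- apply(fluorescence, 2, function(x) all(!is.finite(x)))
  if (any(all_missing))
    stop("substrate(s) with no finite data: ",
         paste(dimnames(fluorescence)[[2]][all_missing], collapse = ", "),
         call. = FALSE)
  structure(list(fluorescence = fluorescence, timepoints = timepoints),
            class = "fret_panel")
}

#' Read a FRET panel from long-format CSV
#'
#' Expected columns: condition, substrate, replicate, time_min,
#' fluorescence.
#'
#' @param path CSV file path.
#' @return `fret_panel`.
#' @export
read_fret_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "substrate", "replicate", "time_min",
            "fluorescence")
  if (!all(need %in% names(df)))
    stop("FRET CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  conds <- unique(df$condition); subs <- unique(df$substrate)
  reps <- sort(unique(df$replicate)); times <- sort(unique(df$time_min))
  arr <- array(NA_real_, c(length(conds), length(subs), length(reps),
                           length(times)),
               dimnames = list(conds, subs, reps, times))
  arr[cbind(match(df$condition, conds), match(df$substrate, subs),
            match(df$replicate, reps), match(df$time_min, times))] <-
    df$fluorescence
  fret_panel(arr, times)
}

#' Cleavage rates from a FRET panel
#'
#' Per condition and substrate: each replicate's fluorescence series is
#' fit by ordinary least squares against time; the replicate slopes are
#' averaged and their SEM retained. Replicates with fewer than two finite
#' timepoints are dropped with a warning; a cell whose replicates all
#' drop is an error.
#'
#' @param panel `fret_panel`.
#' @return list with matrices `rates` (conditions x substrates, AU/min),
#'   `sem`, and `n` (replicates used).
#' @export
cleavage_rates <- function(panel) {
  stopifnot(inherits(panel, "fret_panel"))
  fl <- panel$fluorescence
  tt <- panel$timepoints
  dn <- dimnames(fl)
  nc <- dim(fl)[1]; ns <- dim(fl)[2]; nr <- dim(fl)[3]
  rates <- sem <- nmat <- matrix(NA_real_, nc, ns,
                                 dimnames = dn[1:2])
  dropped <- 0L
  for (i in seq_len(nc)) for (j in seq_len(ns)) {
    slopes <- vapply(seq_len(nr), function(r) {
      y <- fl[i, j, r, ]
      ok <- is.finite(y)
      if (sum(ok) < 2) return(NA_real_)
      .ols_slope(tt[ok], y[ok])
    }, numeric(1))
    dropped <- dropped + sum(is.na(slopes))
    slopes <- slopes[!is.na(slopes)]
    if (!length(slopes))
      stop("all replicates dropped for condition '", dn[[1]][i],
           "', substrate '", dn[[2]][j], "'", call. = FALSE)
    rates[i, j] <- mean(slopes)
    sem[i, j] <- if (length(slopes) > 1)
      stats::sd(slopes) / sqrt(length(slopes)) else NA_real_
    nmat[i, j] <- length(slopes)
  }
  if (dropped > 0)
    warning(dropped, " replicate series dropped (< 2 finite timepoints)",
            call. = FALSE)
  list(rates = rates, sem = sem, n = nmat)
}

## closed-form OLS slope
.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Construct a protease-substrate signature matrix
#'
#' Catalytic efficiencies (per concentration per time) of each candidate
#' protease against each FRET substrate; the basis used to deconvolve
#' observed cleavage rates into specific protease activities.
#'
#' @param x numeric matrix, substrates x proteases, with dimnames;
#'   entries >= 0, no all-zero protease column.
#' @return `signature_matrix` (a validated matrix).
#' @export
signature_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("signature matrix needs substrate rownames and protease colnames",
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("signature entries must be finite and >= 0", call. = FALSE)
  zero <- colSums(x) == 0
  if (any(zero))
    stop("all-zero signature column(s) make protease(s) ",
         paste(colnames(x)[zero], collapse = ", "),
         " indistinguishable", call. = FALSE)
  class(x) <- c("signature_matrix", class(x))
  x
}

#' Read a signature matrix from CSV (substrates x proteases)
#' @param path CSV with a substrate-name first column.
#' @return `signature_matrix`.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  signature_matrix(as.matrix(df))
}

#' Infer specific protease activities from cleavage rates
#'
#' The deconvolution core of protease-activity matrix analysis: for each
#' condition, solves `rates ~ signature %*% activities` by non-negative
#' least squares. Optionally, solutions are averaged over an ensemble of
#' substrate subsets (default all subsets of size `nrow - 1`, i.e.
#' leave-one-substrate-out) and the per-condition dispersion across the
#' ensemble is reported. Rank-deficient subsets are skipped with a log
#' entry.
#'
#' @param rates conditions x substrates matrix (e.g.
#'   `cleavage_rates(panel)$rates`); negative entries (noise) are treated
#'   as zero signal.
#' @param signature `signature_matrix` whose rownames cover the rate
#'   columns.
#' @param ensemble `"none"` for the single full-panel solve, or
#'   `"subsets"` for subset averaging.
#' @param subset_size substrate-subset size for the ensemble (default
#'   all-but-one).
#' @return list of class `activity_table`: `activities` (conditions x
#'   proteases, >= 0), `dispersion` (SD across the ensemble, or NA),
#'   `skipped` (character log of skipped subsets).
#' @export
infer_activities <- function(rates, signature,
                             ensemble = c("none", "subsets"),
                             subset_size = NULL) {
  ensemble <- match.arg(ensemble)
  rates <- as.matrix(rates)
  if (is.null(colnames(rates)))
    stop("rates must have substrate column names", call. = FALSE)
  missing_sub <- setdiff(colnames(rates), rownames(signature))
  if (length(missing_sub))
    stop("substrates absent from signature: ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  sig <- signature[colnames(rates), , drop = FALSE]
  if (nrow(sig) < ncol(sig))
    stop("need at least as many substrates as proteases", call. = FALSE)

  solve_one <- function(A, b) {
    b <- pmax(b, 0)
    pracma::lsqnonneg(A, b)$x
  }

  nprot <- ncol(sig)
  nc <- nrow(rates)
  acts <- matrix(0, nc, nprot,
                 dimnames = list(rownames(rates), colnames(sig)))
  disp <- matrix(NA_real_, nc, nprot,
                 dimnames = dimnames(acts))
  skipped <- character(0)

  if (ensemble == "none") {
    for (i in seq_len(nc)) acts[i, ] <- solve_one(sig, rates[i, ])
  } else {
    k <- subset_size %||% (nrow(sig) - 1L)
    if (k < nprot)
      stop("subset_size must be >= the number of proteases", call. = FALSE)
    subsets <- utils::combn(nrow(sig), k, simplify = FALSE)
    keep <- vapply(subsets, function(s)
      qr(sig[s, , drop = FALSE])$rank == nprot, logical(1))
    skipped <- vapply(subsets[!keep], function(s)
      paste(rownames(sig)[s], collapse = "+"), character(1))
    subsets <- subsets[keep]
    if (!length(subsets))
      stop("every substrate subset is rank-deficient", call. = FALSE)
    for (i in seq_len(nc)) {
      sols <- vapply(subsets, function(s)
        solve_one(sig[s, , drop = FALSE], rates[i, s]), numeric(nprot))
      acts[i, ] <- rowMeans(sols)
      disp[i, ] <- apply(sols, 1, stats::sd)
    }
  }
  structure(list(activities = acts, dispersion = disp, skipped = skipped),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Inferred protease activities (conditions x proteases):\n")
  print(round(x$activities, 4))
  if (length(x$skipped))
    cat("skipped rank-deficient subsets:",
        paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Normalize supernatant shedding responses
#'
#' Background-corrects each raw supernatant value against its
#' metalloproteinase-inhibitor negative control and normalizes to
#' per-cell accumulation: `max(0, raw - background) * volume / cells`.
#' Negative corrected values clamp to zero and are flagged.
#'
#' @param raw conditions x substrates matrix of supernatant
#'   concentrations (e.g. pg/mL).
#' @param cells named vector (or conditions x 1) of viable-cell counts
#'   per condition.
#' @param background conditions x substrates matrix of negative-control
#'   concentrations (a vector recycles across substrates).
#' @param volume_mL supernatant volume.
#' @return list of class `response_table`: `responses` (per-cell units),
#'   `clamped` (logical matrix).
#' @export
normalize_responses <- function(raw, cells, background, volume_mL = 0.1) {
  raw <- as.matrix(raw)
  if (is.vector(background))
    background <- matrix(background, nrow(raw), ncol(raw))
  background <- as.matrix(background)
  if (!all(dim(background) == dim(raw)))
    stop("background must match raw dimensions", call. = FALSE)
  if (is.null(names(cells)) && length(cells) == nrow(raw))
    names(cells) <- rownames(raw)
  missing_cells <- setdiff(rownames(raw), names(cells))
  if (length(missing_cells))
    stop("missing cell count for condition(s): ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  if (any(!is.finite(background)))
    stop("missing background for condition(s): ",
         paste(rownames(raw)[apply(!is.finite(background), 1, any)],
               collapse = ", "), call. = FALSE)
  net <- raw - background
  clamped <- net < 0
  net[clamped] <- 0
  resp <- net * volume_mL / cells[rownames(raw)]
  structure(list(responses = resp, clamped = clamped),
            class = "response_table")
}

#' Correlate inferred protease activities with shedding responses
#'
#' Pairwise Pearson correlation between every protease-activity column
#' and every shedding-response column across a selected set of
#' conditions, with the two-tailed p-value from the t transform
#' `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs are complete-case pairwise; a zero-variance vector yields `NA`
#' (undefined), never 0.
#'
#' @param activities `activity_table` or conditions x proteases matrix.
#' @param responses `response_table` or conditions x substrates matrix.
#' @param conditions optional character/logical selector of conditions
#'   (rows) to use; must leave >= 3.
#' @return list of class `correlation_result`: matrices `r`, `p`, `n`
#'   (proteases x substrates).
#' @export
correlate_csr <- function(activities, responses, conditions = NULL) {
  A <- if (inherits(activities, "activity_table"))
    activities$activities else as.matrix(activities)
  B <- if (inherits(responses, "response_table"))
    responses$responses else as.matrix(responses)
  common <- intersect(rownames(A), rownames(B))
  if (!is.null(conditions))
    common <- if (is.logical(conditions)) common[conditions[common]]
  else intersect(common, conditions)
  if (length(common) < 3)
    stop("need >= 3 shared conditions after selection", call. = FALSE)
  A <- A[common, , drop = FALSE]; B <- B[common, , drop = FALSE]
  np <- ncol(A); ns <- ncol(B)
  r <- p <- nn <- matrix(NA_real_, np, ns,
                         dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(np)) for (j in seq_len(ns)) {
    ok <- is.finite(A[, i]) & is.finite(B[, j])
    n <- sum(ok)
    nn[i, j] <- n
    if (n < 3) next
    a <- A[ok, i]; b <- B[ok, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next # undefined, stays NA
    rv <- stats::cor(a, b)
    r[i, j] <- rv
    tstat <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
    p[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = nn), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson r (proteases x substrates):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Rank candidate sheddases for a substrate
#'
#' Orders proteases by descending Pearson correlation with the
#' substrate's shedding response; ties break by ascending p-value, then
#' by protease label. Undefined correlations are excluded.
#'
#' @param corr `correlation_result`.
#' @param substrate substrate (response column) name.
#' @return data.frame (protease, r, p) in rank order.
#' @export
rank_sheddases <- function(corr, substrate) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!substrate %in% colnames(corr$r))
    stop("unknown substrate '", substrate, "'", call. = FALSE)
  r <- corr$r[, substrate]
  p <- corr$p[, substrate]
  ok <- !is.na(r)
  if (!any(ok))
    stop("no defined correlations for substrate '", substrate, "'",
         call. = FALSE)
  ord <- order(-r[ok], p[ok], names(r)[ok])
  data.frame(protease = names(r)[ok][ord], r = unname(r[ok][ord]),
             p = unname(p[ok][ord]), stringsAsFactors = FALSE)
}
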