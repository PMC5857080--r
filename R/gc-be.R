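#' @title Biodegradation efficiency from GC-FID peak tables
#' @name gc_be
#' @description Residual hydrocarbons in a culture extract are quantified
#'   by GC-FID; peaks are assigned to the n-alkane ladder (C8-C20) by
#'   retention-time matching against a standard run, and degradation of
#'   each alkane is expressed as biodegradation efficiency
#'   \deqn{BE(\%) = 100 - A_s \times 100 / A_{ac}}
#'   where \eqn{A_s} is the peak area in the sample and \eqn{A_{ac}} the
#'   area in the abiotic control.
NULL

#' Construct a chromatogram peak table
#'
#' @param rt retention times in minutes (>= 0)
#' @param area peak areas (>= 0, arbitrary detector units)
#' @param label optional alkane labels (e.g. "n-C12"); NA for unassigned
#' @param id sample identifier
#' @param kind one of "abiotic_control", "sample", "standard"
#' @return a `peak_table` data frame sorted by retention time
#' @export
peak_table <- function(rt, area, label = NA_character_, id = "",
                       kind = c("sample", "abiotic_control", "standard")) {
  kind <- match.arg(kind)
  rt <- as.numeric(rt); area <- as.numeric(area)
  if (any(!is.finite(rt)) || any(rt < 0)) stop("retention times must be >= 0",
                                               call. = FALSE)
  if (any(!is.finite(area)) || any(area < 0)) stop("areas must be >= 0",
                                                   call. = FALSE)
  label <- rep_len(as.character(label), length(rt))
  lab <- label[!is.na(label)]
  if (anyDuplicated(lab)) stop("duplicate peak labels: ",
                               paste(unique(lab[duplicated(lab)]), collapse = ", "),
                               call. = FALSE)
  ord <- order(rt)
  out <- data.frame(rt = rt[ord], area = area[ord], label = label[ord],
                    stringsAsFactors = FALSE)
  structure(out, id = id, kind = kind,
            class = c("peak_table", "data.frame"))
}

#' Read a peak table from CSV
#'
#' Expects columns `rt_min` and `area`, optionally `label`.
#'
#' @param path CSV path
#' @inheritParams peak_table
#' @return a `peak_table`
#' @export
read_peak_csv <- function(path, id = basename(path),
                          kind = c("sample", "abiotic_control", "standard")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rt_min", "area") %in% names(df))) {
    stop("peak CSV needs columns rt_min and area: ", path, call. = FALSE)
  }
  lab <- if ("label" %in% names(df)) df$label else NA_character_
  peak_table(df$rt_min, df$area, lab, id = id, kind = kind)
}

#' Assign alkane labels by retention-time matching
#'
#' Each labelled peak of the standard ladder claims its nearest sample
#' peak within `rt_tol` minutes; every label is assigned at most once and
#' a sample peak can carry at most one label (globally nearest pair
#' wins). Peaks farther than `rt_tol` from every standard peak stay
#' unlabelled. Equidistant ties are resolved deterministically in favour
#' of the earlier-eluting sample peak, with a warning.
#'
#' @param peaks `peak_table` to label
#' @param standard `peak_table` of the alkane standard (all peaks
#'   labelled)
#' @param rt_tol matching tolerance in minutes (default 0.05)
#' @return `peaks` with its `label` column filled where matched
#' @export
match_ladder <- function(peaks, standard, rt_tol = 0.05) {
  stopifnot(inherits(peaks, "peak_table"), inherits(standard, "peak_table"))
  if (any(is.na(standard$label))) {
    stop("every standard peak must be labelled", call. = FALSE)
  }
  cand <- expand.grid(p = seq_len(nrow(peaks)), s = seq_len(nrow(standard)))
  cand$d <- abs(peaks$rt[cand$p] - standard$rt[cand$s])
  cand <- cand[cand$d <= rt_tol, , drop = FALSE]
  # greedy closest-pair assignment; tie-break on earlier sample rt
  cand <- cand[order(cand$d, peaks$rt[cand$p]), , drop = FALSE]
  labels <- rep(NA_character_, nrow(peaks))
  used_s <- logical(nrow(standard))
  used_p <- logical(nrow(peaks))
  i <- 1L
  while (i <= nrow(cand)) {
    p <- cand$p[i]; s <- cand$s[i]
    if (!used_p[p] && !used_s[s]) {
      same_d <- cand$d == cand$d[i] & cand$s == s & !used_p[cand$p]
      if (sum(same_d) > 1) {
        warning("equidistant peaks for ", standard$label[s],
                "; keeping the earlier-eluting peak")
      }
      labels[p] <- standard$label[s]
      used_p[p] <- TRUE
      used_s[s] <- TRUE
    }
    i <- i + 1L
  }
  peaks$label <- labels
  peaks
}

#' Biodegradation efficiency of one peak
#'
#' `BE(%) = 100 - a_s * 100 / a_ac`. Zero when the areas are equal, 100
#' when the compound has vanished from the sample; negative values
#' indicate a grown peak and are returned as-is.
#'
#' @param a_s peak area in the sample (>= 0)
#' @param a_ac peak area in the abiotic control (> 0)
#' @return percentage biodegradation efficiency (<= 100)
#' @export
be_percent <- function(a_s, a_ac) {
  if (any(!is.finite(a_ac)) || any(a_ac <= 0)) {
    stop("control area must be > 0 (BE is undefined otherwise)", call. = FALSE)
  }
  if (any(!is.finite(a_s)) || any(a_s < 0)) {
    stop("sample area must be >= 0", call. = FALSE)
  }
  100 - a_s * 100 / a_ac
}

#' Per-alkane and total biodegradation efficiency
#'
#' Matches both the sample and the abiotic control to the standard
#' ladder, then computes BE for every alkane present in the control.
#' Alkanes absent from the sample count as fully degraded (BE = 100);
#' alkanes found in the sample but not in the control are excluded with a
#' warning. The total BE pools areas:
#' `100 - 100 * sum(A_s) / sum(A_ac)` over the control's alkanes.
#'
#' @param sample,control,standard `peak_table` objects
#' @param rt_tol retention-time matching tolerance in minutes
#' @return a `be_result`: `$table` (alkane, a_s, a_ac, be_percent,
#'   flagged_negative) and `$total_be_percent`
#' @export
be_table <- function(sample, control, standard, rt_tol = 0.05) {
  s <- match_ladder(sample, standard, rt_tol)
  c0 <- match_ladder(control, standard, rt_tol)
  s_lab <- s[!is.na(s$label), ]
  c_lab <- c0[!is.na(c0$label), ]
  extra <- setdiff(s_lab$label, c_lab$label)
  if (length(extra) > 0) {
    warning("alkanes in sample but not in control excluded: ",
            paste(extra, collapse = ", "))
  }
  alk <- c_lab$label
  a_ac <- c_lab$area
  a_s <- s_lab$area[match(alk, s_lab$label)]
  a_s[is.na(a_s)] <- 0
  be <- be_percent(a_s, a_ac)
  tab <- data.frame(alkane = alk, a_s = a_s, a_ac = a_ac, be_percent = be,
                    flagged_negative = be < 0, stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         total_be_percent = 100 - 100 * sum(a_s) / sum(a_ac)),
    class = "be_result"
  )
}

#' @export
print.be_result <- function(x, ...) {
  cat("Biodegradation efficiency (% area loss vs abiotic control)\n")
  print(transform(x$table, be_percent = round(be_percent, 2)))
  cat(sprintf("Total BE over matched alkanes: %.2f%%\n", x$total_be_percent))
  invisible(x)
}
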