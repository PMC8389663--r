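#' Parasitological infection descriptors
#'
#' Standard indices from per-host parasite counts (Bush et al. 1997
#' definitions): prevalence = 100 * infected / examined; mean intensity =
#' total parasites / infected hosts; abundance = total parasites /
#' examined hosts; minimum and maximum intensity over infected hosts
#' only. Values are reported at one decimal (raw values also returned).
#' Abundance never exceeds mean intensity, with equality iff prevalence
#' is 100%.
#'
#' @param counts Non-negative integer vector of parasite counts, one per
#'   examined host, or a data frame with columns `host_id` and `count`
#'   (hosts examined but uninfected listed with count 0).
#' @return List of class `infectionIndices`: `examined`, `infected`,
#'   `total`, `prevalence`, `mean_intensity`, `abundance`,
#'   `min_intensity`, `max_intensity`, plus `raw` (unrounded values).
#'   With no infected host, prevalence is 0 and the intensity fields are
#'   `NA` (with a warning).
#' @examples
#' # 9 examined hosts, 8 infected, 156 parasites in total
#' infectionIndices(c(86, 30, 14, 10, 8, 5, 2, 1, 0))
#' @export
infectionIndices <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) < 1L) stop("need at least one examined host")
  if (any(counts < 0)) stop("counts must be non-negative")
  examined <- length(counts)
  infected <- sum(counts > 0)
  total <- sum(counts)
  if (infected == 0L) {
    warning("no infected hosts: intensity undefined")
    raw <- list(prevalence = 0, mean_intensity = NA_real_,
                abundance = NA_real_, min_intensity = NA_real_,
                max_intensity = NA_real_)
  } else {
    raw <- list(prevalence = 100 * infected / examined,
                mean_intensity = total / infected,
                abundance = total / examined,
                min_intensity = min(counts[counts > 0]),
                max_intensity = max(counts))
  }
  structure(list(examined = examined, infected = infected, total = total,
                 prevalence = round(raw$prevalence, 1L),
                 mean_intensity = round(raw$mean_intensity, 1L),
                 abundance = round(raw$abundance, 1L),
                 min_intensity = raw$min_intensity,
                 max_intensity = raw$max_intensity, raw = raw),
            class = "infectionIndices")
}

#' @export
print.infectionIndices <- function(x, ...) {
  cat(sprintf(paste0("%d parasites on %d/%d hosts: prevalence %.1f%%, ",
                     "mean intensity %.1f, abundance %.1f, range %s-%s\n"),
              x$total, x$infected, x$examined, x$prevalence,
              x$mean_intensity, x$abundance,
              format(x$min_intensity), format(x$max_intensity)))
  invisible(x)
}
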