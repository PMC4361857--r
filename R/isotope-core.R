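# Core data model: delta-notation arithmetic, atomic ratios, CSV IO and
# dataset validation shared by every later stage.

# Canonical isotope channels and the element each one draws its
# concentration from in concentration-dependent mixing.
ISO_CHANNELS <- c("d13C", "d15N", "d34S")
ISO_ELEMENT <- c(d13C = "C", d15N = "N", d34S = "S")

# Atomic masses fixed so C:N etc. are bit-reproducible across platforms.
ATOMIC_MASS <- c(C = 12.011, N = 14.007, S = 32.06)

REGIONS <- c("western", "eastern")
AGE_CLASSES <- c("adult", "subadult", "cub", "unknown_adult_by_bone_size",
                 "unknown")

#' Convert an isotope ratio to delta notation
#'
#' Expresses a heavy/light isotope ratio as a per-mil deviation from an
#' international standard (VPDB for carbon, AIR for nitrogen, VCDT for
#' sulfur): \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}.
#'
#' @param r_sample Isotope ratio of the sample (heavy/light). Must be > 0.
#' @param r_standard Isotope ratio of the standard. Must be > 0.
#' @return Delta value in per mil. Vectorised.
#' @seealso [ratio_from_delta()] for the inverse.
#' @examples
#' delta_from_ratio(1.01, 1)   # 10 permil
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)))
    stop("isotope ratios must be finite")
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Recover an isotope ratio from a delta value
#'
#' @param delta Delta value in per mil (> -1000).
#' @param r_standard Isotope ratio of the standard (> 0).
#' @return The sample ratio. Exact algebraic inverse of [delta_from_ratio()].
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("delta must be finite and > -1000 permil")
  if (any(r_standard <= 0)) stop("standard ratio must be positive")
  (delta / 1000 + 1) * r_standard
}

#' Atomic C:N, C:S and N:S ratios from weight percents
#'
#' Converts collagen elemental composition (weight percent C, N, S) to the
#' atomic ratios used for diagenesis screening. Atomic masses are fixed
#' constants (C 12.011, N 14.007, S 32.06) so results are reproducible to
#' the bit. A zero or missing denominator yields `NA`, never an error.
#'
#' @param pct_C,pct_N,pct_S Weight percents, each in `[0, 100]`; `NA` allowed.
#' @return A data.frame with columns `CN`, `CS`, `NS` (atomic ratios).
#' @examples
#' atomic_ratios(43.0, 15.5, 0.2)
#' @export
atomic_ratios <- function(pct_C, pct_N = NA_real_, pct_S = NA_real_) {
  n <- max(length(pct_C), length(pct_N), length(pct_S))
  pct_C <- rep_len(as.numeric(pct_C), n)
  pct_N <- rep_len(as.numeric(pct_N), n)
  pct_S <- rep_len(as.numeric(pct_S), n)
  bad <- function(x) !is.na(x) & (x < 0 | x > 100)
  if (any(bad(pct_C) | bad(pct_N) | bad(pct_S)))
    stop("weight percents must lie in [0, 100]")
  mol <- function(x, el) x / ATOMIC_MASS[[el]]
  ratio <- function(num, den) {
    r <- num / den
    r[!is.finite(r)] <- NA_real_
    r
  }
  data.frame(
    CN = ratio(mol(pct_C, "C"), mol(pct_N, "N")),
    CS = ratio(mol(pct_C, "C"), mol(pct_S, "S")),
    NS = ratio(mol(pct_N, "N"), mol(pct_S, "S"))
  )
}

#' Read a specimen table from CSV
#'
#' Expected columns: `specimen_id, region, site, year_lo, year_hi, age_class,
#' d13C, d15N, d34S, pct_C, pct_N, pct_S` (blank = missing); an optional
#' `age_years` column carries known ages. Atomic ratio columns `CN`, `CS`,
#' `NS` are derived on read.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data.frame of specimen records.
#' @export
read_specimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "region", "year_lo", "year_hi", "age_class",
            "d13C", "d15N", "d34S", "pct_C", "pct_N", "pct_S")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimens file lacks columns: ", paste(miss, collapse = ", "))
  if (!"age_years" %in% names(df)) df$age_years <- NA_real_
  cbind(df, atomic_ratios(df$pct_C, df$pct_N, df$pct_S))
}

#' Read a diet-item (source) sample table from CSV
#'
#' Expected columns: `sample_id, category, region, d13C, d15N, d34S,
#' pct_C, pct_N, pct_S` (blank = missing).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data.frame of source samples.
#' @export
read_sources <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "category", "region",
            "d13C", "d15N", "d34S", "pct_C", "pct_N", "pct_S")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sources file lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Validate a specimen or source table
#'
#' Report-only check: flags rows with missing required fields, non-finite
#' isotope values, out-of-range weight percents, or unknown region / age
#' class labels. Never mutates its input.
#'
#' @param records A data.frame of specimen or source records.
#' @param type `"specimen"` or `"source"`.
#' @return A data.frame with columns `row`, `id`, `field`, `problem`
#'   (zero rows when everything is valid).
#' @export
validate_dataset <- function(records, type = c("specimen", "source")) {
  type <- match.arg(type)
  rep0 <- data.frame(row = integer(), id = character(),
                     field = character(), problem = character())
  if (!nrow(records)) return(rep0)
  idcol <- if (type == "specimen") "specimen_id" else "sample_id"
  out <- list()
  flag <- function(rows, field, problem) {
    if (!any(rows)) return()
    out[[length(out) + 1L]] <<- data.frame(
      row = which(rows),
      id = as.character(records[[idcol]][rows]),
      field = field, problem = problem)
  }
  if (is.null(records[[idcol]])) stop("missing id column ", idcol)
  flag(is.na(records[[idcol]]) | records[[idcol]] == "", idcol, "missing id")
  flag(!records$region %in% REGIONS, "region", "unknown region label")
  if (type == "specimen" && !is.null(records$age_class))
    flag(!records$age_class %in% AGE_CLASSES, "age_class",
         "unknown age class")
  if (type == "source")
    flag(is.na(records$category) | records$category == "", "category",
         "missing category")
  present <- intersect(ISO_CHANNELS, names(records))
  for (ch in present)
    flag(is.nan(records[[ch]]) | is.infinite(records[[ch]]), ch,
         "non-finite value")
  # every record needs at least one isotope channel
  if (length(present)) {
    none <- Reduce(`&`, lapply(present, function(ch) is.na(records[[ch]])))
    flag(none, "isotopes", "no isotope channel measured")
  }
  for (pc in c("pct_C", "pct_N", "pct_S")) {
    if (is.null(records[[pc]])) next
    flag(!is.na(records[[pc]]) & (records[[pc]] < 0 | records[[pc]] > 100),
         pc, "weight percent outside [0, 100]")
  }
  if (!length(out)) return(rep0)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row), , drop = FALSE]
}

#' Isotope channels measured in every row of a table
#'
#' @param records Data.frame with some of the `d13C`, `d15N`, `d34S` columns.
#' @return Character vector of channels with no missing values.
#' @export
shared_channels <- function(records) {
  present <- intersect(ISO_CHANNELS, names(records))
  present[vapply(present, function(ch) !anyNA(records[[ch]]), logical(1))]
}

#' Pool source samples into per-category groups
#'
#' Computes, for each category, the per-channel mean and standard deviation
#' of the isotope values and the mean elemental concentration (as a fraction
#' of dry mass) used by the concentration-dependent mixing model.
#'
#' @param samples Data.frame of source samples (see [read_sources()]).
#' @param channels Channels to keep; default those measured in all samples.
#' @return An object of class `source_groups`: a list with `names` (K),
#'   `channels` (J), and K x J matrices `mu` (mean, permil), `omega` (SD,
#'   permil), `q` (elemental concentration, fraction), plus counts `n`.
#' @export
source_groups <- function(samples, channels = shared_channels(samples)) {
  if (!length(channels)) stop("no shared isotope channels in samples")
  cats <- sort(unique(samples$category))
  K <- length(cats); J <- length(channels)
  mu <- omega <- q <- matrix(NA_real_, K, J, dimnames = list(cats, channels))
  n <- integer(K); names(n) <- cats
  for (g in cats) {
    rows <- samples[samples$category == g, , drop = FALSE]
    n[g] <- nrow(rows)
    for (ch in channels) {
      mu[g, ch] <- mean(rows[[ch]])
      omega[g, ch] <- if (nrow(rows) > 1) stats::sd(rows[[ch]]) else 0
      pc <- rows[[paste0("pct_", ISO_ELEMENT[[ch]])]]
      q[g, ch] <- mean(pc) / 100
    }
  }
  if (any(!is.finite(q)) || any(q <= 0) || any(q > 1))
    stop("elemental concentrations must be in (0, 100] weight percent")
  structure(list(names = cats, channels = channels,
                 mu = mu, omega = omega, q = q, n = n),
            class = "source_groups")
}

#' @export
print.source_groups <- function(x, ...) {
  cat("Pooled diet-item groups (", length(x$names), " groups, channels: ",
      paste(x$channels, collapse = ", "), ")\n", sep = "")
  for (g in x$names) {
    cat(sprintf("  %-28s n=%-3d ", g, x$n[[g]]))
    cat(paste(sprintf("%s %.2f±%.2f", x$channels, x$mu[g, ], x$omega[g, ]),
              collapse = "  "), "\n")
  }
  invisible(x)
}

# Subset a source_groups object by group name, preserving structure.
subset_source_groups <- function(groups, keep) {
  idx <- match(keep, groups$names)
  if (anyNA(idx)) stop("unknown source group: ",
                       paste(keep[is.na(idx)], collapse = ", "))
  structure(list(names = groups$names[idx], channels = groups$channels,
                 mu = groups$mu[idx, , drop = FALSE],
                 omega = groups$omega[idx, , drop = FALSE],
                 q = groups$q[idx, , drop = FALSE],
                 n = groups$n[idx]),
            class = "source_groups")
}
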