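#' Free-energy profile along a conformational pathway
#'
#' Scores every frame of a pathway with the coarse-grained energy and reports
#' it relative to the first (inactive-endpoint) frame, so `G[1] = 0` by
#' construction. The x-axis is the progress coordinate `s` carried by the
#' pathway.
#'
#' @param path A `cg_pathway` (see [targeted_morph()]).
#' @param p [energy_params()].
#' @param system_label Label stored on the profile.
#' @return An `fe_profile`: tibble with columns `s` and `G` (kcal/mol) and
#'   attributes `system_label`, `endpoints`.
#' @export
build_profile <- function(path, p = energy_params(),
                          system_label = paste(path$endpoints, collapse = "->")) {
  if (length(path$frames) == 0) abort("empty pathway")
  g <- vapply(path$frames, function(f) evaluate_energy(f, p)$total, numeric(1))
  fe_profile(s = path$stats$s, G = g - g[1], system_label = system_label,
             endpoints = path$endpoints)
}

#' Construct a free-energy profile from raw series
#'
#' @param s Strictly increasing progress values in `[0, 1]`.
#' @param G Free energies, kcal/mol, anchored so `G[1] = 0`.
#' @param G_smoothed Optional smoothed series (see [smooth_profile()]).
#' @param system_label,endpoints Metadata carried as attributes.
#' @return An `fe_profile` tibble.
#' @export
fe_profile <- function(s, G, G_smoothed = NULL, system_label = "",
                       endpoints = c("", "")) {
  if (length(s) != length(G)) abort("s and G must have equal length")
  if (length(s) > 1 && any(diff(s) <= 0)) abort("s must be strictly increasing")
  if (abs(G[1]) > 1e-12) abort("G must be anchored at 0 for the first frame")
  out <- tibble(s = s, G = G)
  if (!is.null(G_smoothed)) out$G_smoothed <- G_smoothed
  structure(out, class = c("fe_profile", class(tibble())),
            system_label = system_label, endpoints = endpoints)
}

#' Smooth a profile with a centered moving average
#'
#' Edge windows shrink symmetrically so every point is averaged over an odd
#' number of neighbours; the smoothed series is re-anchored to start at 0.
#'
#' @param prof An `fe_profile`.
#' @param window Odd window width, `1 <= window <= nrow(prof)`; 1 is the
#'   identity.
#' @return The profile with a `G_smoothed` column added.
#' @export
smooth_profile <- function(prof, window = 5L) {
  n <- nrow(prof)
  if (window %% 2 == 0 || window < 1 || window > n) {
    abort("window must be odd and between 1 and the profile length")
  }
  half <- (window - 1L) %/% 2L
  y <- prof$G
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(y[(i - h):(i + h)])
  }, numeric(1))
  sm <- sm - sm[1]
  prof$G_smoothed <- sm
  prof
}

#' Locate intermediate states and transition states on a profile
#'
#' Discrete local minima ("Int") and maxima ("TS") are found by sign changes
#' of the finite differences of `G_smoothed` (if present, else `G`); plateaus
#' collapse to their midpoint and the profile endpoints are candidate minima.
#' Maxima whose barrier over the preceding minimum is below
#' `prominence_threshold` are merged away together with the shallower of the
#' two minima they separated, so minima and maxima strictly alternate in the
#' result.
#'
#' @param prof An `fe_profile`.
#' @param prominence_threshold Minimum barrier (kcal/mol) for a transition
#'   state to be kept; default 0.5.
#' @return A `stationary_report`: list with tibbles `minima` (`label`,
#'   `index`, `s`, `G`) and `maxima` (`label`, `index`, `s`, `G`, `barrier`),
#'   plus `rate_limiting` (label of the largest barrier, ties to the earliest)
#'   and `prominence_threshold`.
#' @export
find_stationary_points <- function(prof, prominence_threshold = 0.5) {
  if (nrow(prof) < 3) abort("profile must have at least 3 points")
  y <- if ("G_smoothed" %in% names(prof)) prof$G_smoothed else prof$G

  # collapse exact plateaus to their midpoint index
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rep_idx <- as.integer(floor((starts + ends) / 2))
  yr <- runs$values

  m <- length(yr)
  kind <- integer(m)  # +1 max, -1 min
  if (m >= 2) {
    if (yr[2] > yr[1]) kind[1] <- -1L
    if (yr[m - 1] > yr[m]) kind[m] <- -1L
    if (m >= 3) {
      for (i in 2:(m - 1)) {
        if (yr[i] > yr[i - 1] && yr[i] > yr[i + 1]) kind[i] <- 1L
        else if (yr[i] < yr[i - 1] && yr[i] < yr[i + 1]) kind[i] <- -1L
      }
    }
  } else {
    kind[1] <- -1L
  }
  keep <- which(kind != 0)
  ext <- tibble(pos = rep_idx[keep], kind = kind[keep], G = yr[keep])

  # prominence merging: repeatedly drop the weakest sub-threshold maximum
  repeat {
    imax <- which(ext$kind == 1L)
    if (length(imax) == 0) break
    barr <- vapply(imax, function(i) ext$G[i] - ext$G[i - 1L], numeric(1))
    weak <- which(barr < prominence_threshold)
    if (length(weak) == 0) break
    k <- imax[weak[which.min(barr[weak])]]
    # drop the maximum and the shallower adjacent minimum
    lo <- k - 1L; hi <- if (k < nrow(ext)) k + 1L else NA_integer_
    drop_min <- if (is.na(hi)) lo else if (ext$G[lo] <= ext$G[hi]) hi else lo
    ext <- ext[-c(k, drop_min), ]
  }

  mins <- ext[ext$kind == -1L, ]
  maxs <- ext[ext$kind == 1L, ]
  minima <- tibble(label = paste0("Int", seq_len(nrow(mins))),
                   index = mins$pos, s = prof$s[mins$pos], G = prof_value(y, mins$pos))
  barriers <- vapply(seq_len(nrow(maxs)), function(i) {
    prev <- mins$G[mins$pos < maxs$pos[i]]
    maxs$G[i] - prev[length(prev)]
  }, numeric(1))
  maxima <- tibble(label = paste0("TS", seq_len(nrow(maxs))),
                   index = maxs$pos, s = prof$s[maxs$pos],
                   G = prof_value(y, maxs$pos), barrier = barriers)
  rate_limiting <- if (nrow(maxima) > 0) {
    maxima$label[which.max(maxima$barrier)]
  } else {
    NA_character_
  }
  structure(list(minima = minima, maxima = maxima,
                 rate_limiting = rate_limiting,
                 prominence_threshold = prominence_threshold),
            class = "stationary_report")
}

prof_value <- function(y, idx) y[idx]

#' @export
print.stationary_report <- function(x, ...) {
  cat(sprintf("<stationary_report> %d minima, %d transition states",
              nrow(x$minima), nrow(x$maxima)))
  if (!is.na(x$rate_limiting)) cat(sprintf(", rate-limiting %s", x$rate_limiting))
  cat("\n")
  if (nrow(x$maxima) > 0) print(x$maxima)
  invisible(x)
}

#' @export
tidy.stationary_report <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$minima, type = "min", barrier = NA_real_),
    mutate(x$maxima, type = "max")
  ) |> arrange(.data$index)
}

#' @export
glance.stationary_report <- function(x, ...) {
  tibble(n_minima = nrow(x$minima), n_ts = nrow(x$maxima),
         rate_limiting = x$rate_limiting,
         max_barrier = if (nrow(x$maxima)) max(x$maxima$barrier) else NA_real_)
}

#' Activation barriers and the rate-limiting transition state
#'
#' Each barrier is the free-energy rise from the minimum preceding the
#' transition state: `dG_k = G(TS_k) - G(preceding Int)`. The rate-limiting
#' step attains the largest barrier (ties break to the earliest TS).
#'
#' @param rep A `stationary_report`.
#' @return A list with `barriers` (tibble `label`, `s`, `barrier`) and
#'   `rate_limiting` (label or `NA` when the profile has no TS).
#' @export
barriers_and_rate_limiting <- function(rep) {
  list(barriers = rep$maxima[, c("label", "s", "barrier")],
       rate_limiting = rep$rate_limiting)
}

#' Serialise a stationary report as JSON
#'
#' @param rep A `stationary_report`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_stationary_json <- function(rep, path) {
  obj <- list(minima = rep$minima, transition_states = rep$maxima,
              rate_limiting = rep$rate_limiting,
              prominence_threshold = rep$prominence_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a profile as TSV (columns s, G_kcal_mol, G_smoothed)
#'
#' @param prof An `fe_profile`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(prof, path) {
  out <- tibble(s = prof$s, G_kcal_mol = prof$G,
                G_smoothed = if ("G_smoothed" %in% names(prof)) prof$G_smoothed
                             else NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a free-energy profile with its stationary points
#'
#' @param object An `fe_profile`.
#' @param report Optional `stationary_report` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_profile <- function(object, report = NULL, ...) {
  df <- as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$G)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "conformational progress s",
                  y = "free energy (kcal/mol)",
                  title = attr(object, "system_label")) +
    ggplot2::theme_minimal()
  if ("G_smoothed" %in% names(df)) {
    gg <- gg + ggplot2::geom_line(ggplot2::aes(y = .data$G_smoothed),
                                  colour = "steelblue")
  }
  if (!is.null(report)) {
    pts <- tidy(report)
    gg <- gg + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$s, y = .data$G, colour = .data$type),
      size = 2.5) +
      ggplot2::geom_text(data = pts,
                         ggplot2::aes(x = .data$s, y = .data$G, label = .data$label),
                         vjust = -1, size = 3)
  }
  gg
}
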