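# Published species-level summary statistics for the validation sample of
# 36 cercopithecoid second mandibular molars: per-species sample size and
# the mean and SD of elevation-grid OPCR (DEM-OPCR), mesh-based OPCR
# (3D-OPCR), and their per-specimen difference (delta OPCR).
species_opcr_moments <- function() {
  data.frame(
    species = c("Cercocebus atys", "Cercopithecus mitis",
                "Colobus guereza", "Theropithecus gelada"),
    n = c(7L, 10L, 10L, 9L),
    dem_mean = c(57.41, 56.10, 54.10, 56.51),
    dem_sd = c(6.932, 3.026, 4.001, 4.534),
    td_mean = c(75.71, 69.75, 70.91, 86.35),
    td_sd = c(13.798, 7.961, 9.134, 8.992),
    delta_mean = c(18.30, 13.65, 16.81, 29.83),
    delta_sd = c(9.133, 6.320, 6.739, 6.091))
}

# deterministic length-n vectors with exact sample mean 0, sample SD 1 and
# exact zero correlation (Gram-Schmidt on the linear and quadratic ramps)
orthonormal_scores <- function(n) {
  z1 <- seq_len(n)
  z1 <- (z1 - mean(z1)) / stats::sd(z1)
  w <- seq_len(n)^2
  w <- w - mean(w)
  w <- w - sum(w * z1) / sum(z1 * z1) * z1
  cbind(z1, w / stats::sd(w))
}

#' Synthetic per-specimen OPCR table
#'
#' The raw per-specimen surface meshes behind the published four-species
#' molar complexity comparison are not distributed, so this function
#' reconstructs a synthetic stand-in table of 36 specimens (7/10/10/9 per
#' species). The reconstruction is deterministic and moment-matched: within
#' every species the sample means and SDs of DEM-OPCR and 3D-OPCR equal the
#' published values exactly, and the within-species correlation between the
#' two treatments is solved so that the SD of their difference (delta OPCR)
#' also matches. One-way ANOVA, Tukey HSD and ordinary least squares on
#' these data depend on the sample only through exactly these moments, so
#' every published test statistic is reproduced up to the rounding of the
#' published summary table. The values are synthetic: individual rows are
#' not the real specimens.
#'
#' @return data.frame with columns `specimen`, `species`, `dem_opcr`,
#'   `td_opcr`, `delta_opcr` (always recomputed as `td_opcr - dem_opcr`).
#' @export
synthetic_specimen_table <- function() {
  mom <- species_opcr_moments()
  rows <- lapply(seq_len(nrow(mom)), function(i) {
    n <- mom$n[i]
    r <- (mom$td_sd[i]^2 + mom$dem_sd[i]^2 - mom$delta_sd[i]^2) /
      (2 * mom$td_sd[i] * mom$dem_sd[i])
    if (abs(r) > 1)
      stop("published moments are inconsistent for species ", mom$species[i])
    z <- orthonormal_scores(n)
    td <- mom$td_mean[i] + mom$td_sd[i] * z[, 1L]
    dem <- mom$dem_mean[i] +
      mom$dem_sd[i] * (r * z[, 1L] + sqrt(1 - r^2) * z[, 2L])
    abbr <- gsub("[^A-Za-z]", "", abbreviate(mom$species[i], 8))
    data.frame(specimen = sprintf("%s_%02d", abbr, seq_len(n)),
               species = mom$species[i],
               dem_opcr = dem, td_opcr = td)
  })
  out <- do.call(rbind, rows)
  out$delta_opcr <- out$td_opcr - out$dem_opcr
  rownames(out) <- NULL
  out
}

#' Load a per-specimen OPCR table
#'
#' Reads a tab-separated table with columns `specimen`, `species`,
#' `DEM_OPCR`, `OPCR3D` (case-insensitive). The treatment difference is
#' always recomputed from the two treatment columns, never trusted from
#' the file.
#'
#' @param path TSV file path.
#' @return data.frame in the format of [synthetic_specimen_table()].
#' @export
load_specimen_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("specimen", "species", "dem_opcr", "opcr3d")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("specimen table is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(specimen = as.character(tab$specimen),
                    species = as.character(tab$species),
                    dem_opcr = as.numeric(tab$dem_opcr),
                    td_opcr = as.numeric(tab$opcr3d))
  if (anyNA(out$dem_opcr) || anyNA(out$td_opcr))
    stop("specimen table contains non-numeric OPCR values")
  out$delta_opcr <- out$td_opcr - out$dem_opcr
  out
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition of `values` by `groups`, via
#' [stats::aov()]. Used to test whether a topographic metric differs
#' between species.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor); at least 2 groups with
#'   at least 2 observations each.
#' @return list of class `anova_fit` with `F`, `df_between`, `df_within`,
#'   `ms_between`, `ms_within`, `p`, and the underlying `aov` fit.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("`values` and `groups` lengths differ")
  cnt <- table(groups)
  if (length(cnt) < 2L) stop("need at least 2 groups")
  if (any(cnt < 2L))
    stop("every group needs at least 2 observations (offender: ",
         names(cnt)[cnt < 2L][1L], ")")
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tab <- stats::anova(fit)
  structure(list(F = tab$`F value`[1L],
                 df_between = tab$Df[1L],
                 df_within = tab$Df[2L],
                 ms_between = tab$`Mean Sq`[1L],
                 ms_within = tab$`Mean Sq`[2L],
                 p = tab$`Pr(>F)`[1L],
                 fit = fit),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("<anova_fit: F(%d, %d) = %.3f, MSb = %.3f, MSw = %.3f, p = %.4g>\n",
              x$df_between, x$df_within, x$F, x$ms_between, x$ms_within, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons of group means with studentized-range adjusted
#' p values, via [stats::TukeyHSD()]. For unbalanced designs this is the
#' Tukey-Kramer adjustment (also what mainstream statistics packages
#' apply); the significance flag uses alpha = 0.05.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with `group1`, `group2`, `diff` (absolute mean
#'   difference), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  fit <- one_way_anova(values, groups)$fit
  tk <- stats::TukeyHSD(fit)$groups
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pair, `[`, "", 2L),
             group2 = vapply(pair, `[`, "", 1L),
             diff = abs(tk[, "diff"]),
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' Ordinary least squares line
#'
#' Simple linear regression `y ~ x` via [stats::lm()], reporting the slope,
#' intercept, coefficient of determination, and the p value of the slope's
#' t statistic. Used for the regressions of the treatment difference
#' (delta OPCR) on each OPCR treatment.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("`x` has zero variance; slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]))
}

#' Species-level validation summary
#'
#' Convenience wrapper reproducing the full statistical comparison of the
#' two OPCR treatments from a per-specimen table: per-species descriptive
#' statistics, one-way ANOVAs (each treatment and their difference, with a
#' species factor), Tukey HSD pairwise tests, and the regressions of the
#' treatment difference on each treatment.
#'
#' @param table data.frame as returned by [synthetic_specimen_table()] or
#'   [load_specimen_table()].
#' @return list with `descriptives`, `anova_dem`, `anova_td`,
#'   `anova_delta`, `tukey_td`, `tukey_delta`, `fit_delta_on_td`,
#'   `fit_delta_on_dem`.
#' @export
validate_opcr_treatments <- function(table = synthetic_specimen_table()) {
  stopifnot(all(c("species", "dem_opcr", "td_opcr") %in% names(table)))
  table$delta_opcr <- table$td_opcr - table$dem_opcr
  agg <- function(v) {
    d <- stats::aggregate(v, list(species = table$species),
                          function(z) c(mean = mean(z), sd = stats::sd(z)))
    cbind(d["species"], as.data.frame(d$x))
  }
  desc <- Reduce(function(a, b) merge(a, b, by = "species"),
                 list(stats::setNames(agg(table$dem_opcr),
                                      c("species", "dem_mean", "dem_sd")),
                      stats::setNames(agg(table$td_opcr),
                                      c("species", "td_mean", "td_sd")),
                      stats::setNames(agg(table$delta_opcr),
                                      c("species", "delta_mean", "delta_sd"))))
  desc$n <- as.vector(table(table$species)[desc$species])
  list(descriptives = desc,
       anova_dem = one_way_anova(table$dem_opcr, table$species),
       anova_td = one_way_anova(table$td_opcr, table$species),
       anova_delta = one_way_anova(table$delta_opcr, table$species),
       tukey_td = tukey_hsd(table$td_opcr, table$species),
       tukey_delta = tukey_hsd(table$delta_opcr, table$species),
       fit_delta_on_td = linear_fit(table$td_opcr, table$delta_opcr),
       fit_delta_on_dem = linear_fit(table$dem_opcr, table$delta_opcr))
}
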