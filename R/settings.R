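#' Design settings for fragment and primer design
#'
#' Bundles every tunable parameter of the design pipeline. Defaults follow
#' common dsDNA synthesis provider specifications (fragments of 300-1500 bp)
#' and standard IVA cloning practice (homology flanks of at least 15 bp with
#' a melting temperature between 47 and 52 degrees Celsius).
#'
#' @param min_fragment_bp Minimum orderable fragment length in bp (default 300).
#' @param max_fragment_bp Maximum orderable fragment length in bp (default 1500).
#' @param min_flank_bp Minimum homology flank length in bp (default 15).
#' @param flank_tm_window Numeric length-2: target Tm window for flanks in
#'   degrees Celsius (default \code{c(47, 52)}).
#' @param optimization_mode Either \code{"quantity"} (fewest fragment regions,
#'   i.e. fewest linearization PCRs) or \code{"length"} (smallest total region
#'   length, i.e. cheapest synthesis).
#' @param cost_per_bp Synthesis cost per base pair, in your ordering currency
#'   (default 0.05).
#' @param silent_markers_per_end Number of silent marker codons placed near
#'   each end of the mutant region (default 2).
#' @param random_seed Integer seed recorded with the design for provenance.
#' @param primer_len_range Integer length-2: primer length scan range
#'   (default \code{c(18, 30)}).
#' @param primer_tm_window Numeric length-2: primer Tm window in degrees
#'   Celsius (default \code{c(57, 63)}).
#' @param primer_gc_window Numeric length-2: allowed primer GC fraction
#'   (default \code{c(0.40, 0.60)}).
#' @param primer_pair_dtm_max Maximum Tm difference within a linearization
#'   primer pair, in degrees Celsius (default 3).
#' @param sequencing_spacing_bp Spacing between consecutive sequencing
#'   primers (default 500, leaving margin on a typical 800 bp read).
#' @param max_flank_bp Upper bound for the flank length scan (default 60).
#'
#' @return An object of class \code{design_settings} (a validated list).
#' @examples
#' s <- design_settings()
#' s$max_fragment_bp
#' @export
design_settings <- function(min_fragment_bp = 300L,
                            max_fragment_bp = 1500L,
                            min_flank_bp = 15L,
                            flank_tm_window = c(47, 52),
                            optimization_mode = c("quantity", "length"),
                            cost_per_bp = 0.05,
                            silent_markers_per_end = 2L,
                            random_seed = 42L,
                            primer_len_range = c(18L, 30L),
                            primer_tm_window = c(57, 63),
                            primer_gc_window = c(0.40, 0.60),
                            primer_pair_dtm_max = 3,
                            sequencing_spacing_bp = 500L,
                            max_flank_bp = 60L) {
  optimization_mode <- match.arg(optimization_mode)
  s <- list(
    min_fragment_bp = as.integer(min_fragment_bp),
    max_fragment_bp = as.integer(max_fragment_bp),
    min_flank_bp = as.integer(min_flank_bp),
    flank_tm_window = as.numeric(flank_tm_window),
    optimization_mode = optimization_mode,
    cost_per_bp = as.numeric(cost_per_bp),
    silent_markers_per_end = as.integer(silent_markers_per_end),
    random_seed = as.integer(random_seed),
    primer_len_range = as.integer(primer_len_range),
    primer_tm_window = as.numeric(primer_tm_window),
    primer_gc_window = as.numeric(primer_gc_window),
    primer_pair_dtm_max = as.numeric(primer_pair_dtm_max),
    sequencing_spacing_bp = as.integer(sequencing_spacing_bp),
    max_flank_bp = as.integer(max_flank_bp)
  )
  if (s$min_fragment_bp <= 0L || s$min_fragment_bp > s$max_fragment_bp) {
    stop("need 0 < min_fragment_bp <= max_fragment_bp", call. = FALSE)
  }
  if (s$min_flank_bp < 1L) stop("min_flank_bp must be >= 1", call. = FALSE)
  if (length(s$flank_tm_window) != 2L || s$flank_tm_window[1] > s$flank_tm_window[2]) {
    stop("flank_tm_window must be c(low, high) with low <= high", call. = FALSE)
  }
  if (s$min_fragment_bp < 2L * s$min_flank_bp + 3L) {
    stop("min_fragment_bp leaves no room for flanks plus one codon", call. = FALSE)
  }
  if (s$silent_markers_per_end < 0L) stop("silent_markers_per_end must be >= 0", call. = FALSE)
  if (s$primer_len_range[1] < 15L || s$primer_len_range[2] > 36L ||
      s$primer_len_range[1] > s$primer_len_range[2]) {
    stop("primer_len_range must lie within [15, 36]", call. = FALSE)
  }
  class(s) <- "design_settings"
  s
}

# usable interior (region) length floor implied by the settings
core_min_bp <- function(settings) {
  settings$min_fragment_bp - 2L * settings$min_flank_bp
}

# region + flank budget ceiling for the wild-type (net-indel 0) case
core_max_bp <- function(settings) {
  settings$max_fragment_bp - 2L * settings$min_flank_bp
}

#' Read design settings from a YAML file
#'
#' The file is a flat YAML mapping with any subset of the arguments of
#' \code{\link{design_settings}}; missing keys take their defaults.
#'
#' @param path Path to a YAML settings file.
#' @return A \code{design_settings} object.
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) stop("settings file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(design_settings))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown settings key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(design_settings, vals)
}

#' @export
print.design_settings <- function(x, ...) {
  cat("design_settings\n")
  cat(sprintf("  fragment length: %d-%d bp, flanks >= %d bp (Tm %.1f-%.1f C)\n",
              x$min_fragment_bp, x$max_fragment_bp, x$min_flank_bp,
              x$flank_tm_window[1], x$flank_tm_window[2]))
  cat(sprintf("  optimization: %s, cost %.3f per bp, %d silent markers per end\n",
              x$optimization_mode, x$cost_per_bp, x$silent_markers_per_end))
  cat(sprintf("  primers: %d-%d nt, Tm %.1f-%.1f C, GC %.2f-%.2f\n",
              x$primer_len_range[1], x$primer_len_range[2],
              x$primer_tm_window[1], x$primer_tm_window[2],
              x$primer_gc_window[1], x$primer_gc_window[2]))
  invisible(x)
}
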