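#' Pipeline configuration with documented defaults
#'
#' Every tunable threshold of the caller in one list. Defaults: seed length
#' `k = 21` for genome/transcript alignment (`hum_k = 15` for half-reads
#' and junction scanning, and a `k = 10` fallback applies automatically to
#' reads shorter than the seed), `max_mismatch = 2` per end,
#' `max_hits = 5`, proper-pair insert ceiling `max_insert = 10000` bp,
#' 3'-overlap trimming threshold 20% with 5-nt steps down to 30 nt,
#' small-indel rescue up to `max_gap = 5` nt, flanking allowance
#' `FLB = 5` nt in the span-read interval formulas, junction flank
#' `W = read length` with `min_flank = 30` nt, support thresholds
#' `min_span = 2` and `min_junc = 2` with `min_overhang = 8` nt, homology
#' filters at 90% identity over a 100-nt window, and a 10-kb proximity
#' guard.
#'
#' @param ... Named overrides of any default.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(...) {
  cfg <- list(
    k = 21L, hum_k = 15L, short_k = 10L,
    max_mismatch = 2L, max_hits = 5L,
    max_insert = 10000L,
    INS = NULL, SD = NULL,            # estimated from PE-S01 when NULL
    robust_insert = TRUE, insert_peak_halfwidth = 50,
    trim_threshold = 0.20, force_trim = FALSE,
    trim_step = 5L, trim_min_len = 30L,
    max_gap = 5L,
    FLB = 5L,
    hum_min_half = 20L,
    W = NULL,                         # junction flank; NULL = read length
    min_flank = 30L,
    min_span = 2L, min_junc = 2L, min_overhang = 8L,
    homology_window = 100L, homology_identity = 0.90,
    min_gene_distance = 10000L,
    junction_flank_homology = 60L,
    families = NULL,
    sample_id = "sample")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "fusion_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [fusion_config()] fields; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `fusion_config` list.
#' @export
read_fusion_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(fusion_config, vals %||% list())
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "(auto)" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
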