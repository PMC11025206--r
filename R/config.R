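#' Full-pipeline configuration
#'
#' One strict, JSON-serializable configuration object for the simulate →
#' segment → analyse pipeline.  Each section holds overrides for the
#' corresponding constructor's arguments ([cohort_spec()],
#' [phantom_spec()], [segmentation_config()] / [gmm_control()]); unknown
#' keys are rejected at construction so a typo cannot silently fall back
#' to a default.
#'
#' @param cohort Named list of [cohort_spec()] overrides.
#' @param phantom Named list of [phantom_spec()] overrides.
#' @param segmentation Named list of [segmentation_config()] overrides;
#'   an optional `gmm` sub-list holds [gmm_control()] overrides.
#' @param stats Named list: `fwe` (`"bonferroni"` or `"holm"`) and
#'   `alpha`.
#' @param seed Master seed; every stage's randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), phantom = list(),
                            segmentation = list(),
                            stats = list(fwe = "bonferroni", alpha = 0.05),
                            seed = 1L) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("validation error in `", where, "`: unknown field(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(cohort, setdiff(names(formals(cohort_spec)), "seed"),
             "cohort")
  check_keys(phantom, setdiff(names(formals(phantom_spec)), "seed"),
             "phantom")
  seg_allowed <- c(setdiff(names(formals(segmentation_config)),
                           c("seed", "gmm")), "gmm")
  check_keys(segmentation, seg_allowed, "segmentation")
  if (!is.null(segmentation$gmm))
    check_keys(segmentation$gmm,
               setdiff(names(formals(gmm_control)), "seed"),
               "segmentation$gmm")
  stats <- modifyList(list(fwe = "bonferroni", alpha = 0.05), stats)
  check_keys(stats, c("fwe", "alpha"), "stats")
  if (!stats$fwe %in% c("bonferroni", "holm"))
    stop("validation error in `stats`: fwe must be bonferroni or holm",
         call. = FALSE)
  if (is.null(seed) || !is.finite(seed))
    stop("validation error: `seed` is required", call. = FALSE)
  structure(list(cohort = cohort, phantom = phantom,
                 segmentation = segmentation, stats = stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The JSON round trip is lossless: reading a written configuration
#' reproduces the object (and therefore the run) exactly.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns the validated [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # named atomic vectors must become JSON objects, not bare arrays, so
  # that group names survive the round trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namify(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("validation error: unknown top-level field(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  # collapse single-type named lists (written by write_config) back to
  # named vectors
  devec <- function(x) {
    if (!is.list(x)) return(x)
    if (length(x) && !is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L &&
                     !is.list(e), logical(1))) &&
        length(unique(vapply(x, typeof, character(1)))) == 1L)
      return(unlist(x))
    lapply(x, devec)
  }
  for (sec in c("cohort", "phantom"))
    if (!is.null(raw[[sec]])) raw[[sec]] <- lapply(raw[[sec]], devec)
  if (!is.null(raw$segmentation$gmm))
    raw$segmentation$gmm <- as.list(raw$segmentation$gmm)
  do.call(pipeline_config, raw)
}

# short content hash identifying the effective configuration; stamped
# into every output artifact
config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1L, 12L)
}

# per-subject child seeds, kept inside 32-bit integer range
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 48271 + 7919 * seq_len(n)) %%
               .Machine$integer.max)
}
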