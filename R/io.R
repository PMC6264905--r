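#' Read plate-reader growth curves from long-format TSV
#'
#' Expects columns `time_min`, `od`, `strain`, `condition`, `replicate`;
#' one [growth_curve()] is built per (strain, condition, replicate).
#'
#' @param path Path to the TSV file.
#' @return List of [growth_curve()] objects.
#' @export
read_growth_tsv <- function(path) {
  tab <- read_tsv(path)
  need <- c("time_min", "od", "strain", "condition", "replicate")
  if (!all(need %in% names(tab))) {
    stop("growth TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- interaction(tab$strain, tab$condition, tab$replicate, drop = TRUE)
  lapply(split(tab, key), function(d) {
    d <- d[order(d$time_min), ]
    growth_curve(d$time_min, d$od, strain_id = d$strain[1],
                 condition = d$condition[1], replicate = d$replicate[1])
  })
}

#' Read two-color competition trajectories from TSV
#'
#' Expects columns `line_id`, `generation`, `green_freq`.
#'
#' @param path Path to the TSV file.
#' @return List of [competition_trajectory()] objects.
#' @export
read_trajectories_tsv <- function(path) {
  tab <- read_tsv(path)
  need <- c("line_id", "generation", "green_freq")
  if (!all(need %in% names(tab))) {
    stop("trajectory TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(tab, tab$line_id), function(d) {
    d <- d[order(d$generation), ]
    competition_trajectory(d$generation, d$green_freq, line_id = d$line_id[1])
  })
}

#' Load a supplementary-derived data table
#'
#' The quantitative reproduction of the source study's reported statistics
#' needs its supplementary data tables, which are distributed as
#' spreadsheets and are not redistributable with this package. To run those
#' checks, export the relevant sheets as tab-separated text into a
#' directory (default: `inst/extdata/supplementary/` of the source tree, or
#' the installed `extdata/supplementary/`) using the documented layouts:
#'
#' * `fig2c_improvements.tsv` — `group` (`ylip`/`scer`), `population`,
#'   `improvement_percent`: per-population fitness improvements in rich
#'   medium behind the Welch t comparison.
#' * `fig3b_paired.tsv` — `clone`, `improvement_ylip`, `improvement_scer`:
#'   the paired improvements of each evolved clone with the replacement vs
#'   native plasmid.
#' * `s9_e7_segregants.tsv` — `spore`, `fitness_37c`, `fitness_guhcl`:
#'   F1 segregant fitness of the E7 backcross in the two assay conditions.
#' * `s2_fitness.tsv` — `strain`, `group`, `condition`, `replicate`,
#'   `rate`: the full strain-by-condition fitness measurements.
#' * `s10_pool_freqs.tsv` — `clone`, `locus`, `good_freq`, `bad_freq`:
#'   segregant-pool allele frequencies for the mapped clones.
#' * `s6_mutations.tsv` — `clone`, `chromosome`, `position`, `ref`, `alt`,
#'   `gene`, `effect`: the evolved-clone mutation list.
#'
#' @param name File name (one of the layouts above).
#' @param dir Directory holding the exported tables; defaults to the
#'   installed `extdata/supplementary/`.
#' @return Data frame.
#' @export
load_supplementary <- function(name, dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "supplementary", package = "hubevolve")
  }
  path <- file.path(dir, name)
  if (!nzchar(dir) || !file.exists(path)) {
    stop("supplementary table '", name, "' not found; export the ",
         "spreadsheet sheet as TSV into extdata/supplementary/ ",
         "(see ?load_supplementary for the expected columns)", call. = FALSE)
  }
  read_tsv(path)
}
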