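#' The 34-complex benchmark table
#'
#' Experimental binding free energies and published per-complex predictions
#' for the 34 protein-ligand complexes of the benchmark set (a subset of
#' the PRO_LEADS calibration set; metalloproteins excluded). Columns:
#' `pdb_id`, `protein_name`, `dg_exptl`, and the predictions of the simple
#' two-parameter model (`dg_simple`), the solvent-free direct interaction
#' approximation (`dg_diav`) and the solvent-aware variant (`dg_dias`), all
#' kcal/mol, from leave-one-out cross-validation with the LJ 8-4 form and
#' the ASA entropy property.
#'
#' @return Tibble with 34 rows. The loader verifies row count and column
#'   checksums, so a corrupted installation fails loudly.
#' @examples
#' b <- benchmark_table4()
#' dg_metrics(b$dg_dias, b$dg_exptl)
#' @export
benchmark_table4 <- function() {
  path <- system.file("extdata", "benchmark_dg.tsv", package = "diascore",
                      mustWork = TRUE)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sums <- c(dg_exptl = -305.78, dg_simple = -293.17,
            dg_diav = -305.86, dg_dias = -307.19)
  ok <- nrow(d) == 34 &&
    all(abs(vapply(names(sums), function(cl) sum(d[[cl]]), 0) - sums) < 1e-9)
  if (!ok) {
    abort("Packaged benchmark table failed its checksum.",
          class = "diascore_fixture_error")
  }
  d
}

#' Metrics of each published prediction column against experiment
#'
#' @param table Benchmark tibble (default [benchmark_table4()]).
#' @return Tibble with one row per model column: `model`, `mae`,
#'   `pearson_r`.
#' @export
benchmark_metrics <- function(table = benchmark_table4()) {
  cols <- c(simple = "dg_simple", diav = "dg_diav", dias = "dg_dias")
  dplyr::bind_rows(lapply(names(cols), function(m) {
    dplyr::mutate(dg_metrics(table[[cols[[m]]]], table$dg_exptl),
                  model = m, .before = 1)
  }))
}
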