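# shared fixture loaders; all fixtures are plain-text tables under extdata

extdata_path <- function(file) {
  system.file("extdata", file, package = "pharmprev", mustWork = TRUE)
}

load_registry <- function() {
  read_ddd_registry(extdata_path("ddd_registry_a10_synthetic.csv"))
}

load_population <- function() {
  read_population(extdata_path("population_portugal.csv"))
}

# the printed national DID table; `level` slices the level-3 insulin/NAD
# split (model input) or the level-4 class rows (reporting input)
national_consumption <- function(level = 3) {
  tbl <- readr::read_csv(extdata_path("national_did_a10.csv"),
                         show_col_types = FALSE)
  width <- c(`2` = 3L, `3` = 4L, `4` = 5L)[[as.character(level)]]
  dplyr::filter(tbl, nchar(atc_class) == width)
}

national_population <- function() {
  pop <- load_population()
  out <- dplyr::summarise(dplyr::group_by(pop, year),
                          inhabitants = sum(inhabitants), .groups = "drop")
  dplyr::mutate(out, region = "TOTAL")
}

# a tiny two-drug registry for hand-arithmetic tests
mini_registry <- function() {
  ddd_registry(tibble::tibble(
    atc = c("A10BA02", "A10AE04", "A10BD07"),
    ddd_quantity = c(2000, 40, 2),
    ddd_unit = c("mg", "IU", "UD"),
    route = c("oral", "parenteral", "oral")
  ))
}
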