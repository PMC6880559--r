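#' Load the published count tables shipped with the package
#'
#' Fixed fixtures used by the statistics modules and their regression tests:
#' * `table1`: the per-bin sharing tallies (as an `alu_sharing_bins`);
#' * `table2`: species-indicative counts, intergeneric overlap, printed
#'   percentages, z-scores and one-tailed p-values (data.frame);
#' * `validation_counts`: marginal counts of the PCR validation (named list);
#' * `ascertainment`: pre- and post-filter ascertainment totals (data.frame).
#'
#' @param name one of `"table1"`, `"table2"`, `"validation_counts"`,
#'   `"ascertainment"`.
#' @return See above.
#' @export
load_fixture_tables <- function(name = c("table1", "table2",
                                         "validation_counts",
                                         "ascertainment")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "alushare",
                                  mustWork = TRUE)
  switch(name,
    table1 = {
      f <- path("table1_sharing_bins.tsv")
      lines <- readLines(f)
      meta <- grep("^#(species|clade)\t", lines, value = TRUE)
      species <- strsplit(sub("^#species\t-\t", "", meta[1]), "\t")[[1]]
      clade <- strsplit(sub("^#clade\t-\t", "", meta[2]), "\t")[[1]]
      df <- read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
      counts <- as.matrix(df[, -(1:2)])
      rownames(counts) <- df$bin
      sharing_bins(counts, df$total, species = species, clade = clade)
    },
    table2 = read.delim(path("table2_species_indicative.tsv"),
                        comment.char = "#", stringsAsFactors = FALSE),
    validation_counts = {
      df <- read.delim(path("validation_counts.tsv"), comment.char = "#",
                       stringsAsFactors = FALSE)
      as.list(structure(df$value, names = df$key))
    },
    ascertainment = read.delim(path("ascertainment_totals.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE))
}
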