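# Published summary tables from the rhesus placenta full-length cDNA
# survey this package models, bundled as plain-text fixtures.  They are
# inputs (printed counts and coordinates), used to check the package's
# arithmetic against the published layout.

#' Published survey tables bundled with the package
#'
#' Accessors for the printed summary tables of the rhesus placenta
#' full-length cDNA survey: per-category cDNA/gene counts
#' (`"categories"`), the 60-row genome-mapping table of unknown
#' transcripts (`"genome_hits"`), per-region INDEL transcript counts
#' (`"indels"`), and per-category consensus identity means
#' (`"identities"`).
#'
#' @param which One of `"categories"`, `"genome_hits"`, `"indels"`,
#'   `"identities"`.
#' @return The requested table as a data frame.
#' @export
survey_table <- function(which = c("categories", "genome_hits",
                                   "indels", "identities")) {
  which <- match.arg(which)
  file <- switch(which,
                 categories = "survey_category_counts.tsv",
                 genome_hits = "survey_genome_hits.tsv",
                 indels = "survey_indel_counts.tsv",
                 identities = "survey_identity_means.tsv")
  path <- system.file("extdata", file, package = "flcdna")
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
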