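#' Write identified subnetworks to a results directory
#'
#' Produces \code{subnetworks.tsv} (one row per subnetwork: gene set, seed,
#' strategy, \code{;}-joined members/signs/parents, F value, size), one
#' \code{edges_<set>_<seed>.tsv} parent-to-child edge list per subnetwork
#' with more than one member, and \code{manifest.json} echoing the search
#' configuration and software version. The manifest is deterministic:
#' identical inputs and configuration reproduce byte-identical files.
#'
#' @param subnetworks list of \linkS4class{Subnetwork}, or a
#'   \code{"SubnetworkRun"} (its representatives are written and its config
#'   recorded).
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{searchConfig}} for the manifest; taken from
#'   a run automatically.
#' @param inputs optional named list of input file paths; their md5 sums go
#'   in the manifest.
#' @return Invisibly, the summary TSV path.
#' @export
writeSubnetworks <- function(subnetworks, outDir, config = NULL,
                             inputs = NULL) {
    if (inherits(subnetworks, "SubnetworkRun")) {
        if (is.null(config))
            config <- subnetworks$config
        subnetworks <- subnetworks$representatives
    }
    if (length(subnetworks) == 0L)
        stop("no subnetworks to write")
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory: %s", outDir))
    rows <- lapply(subnetworks, function(s) data.frame(
        gene_set_id = geneSetId(s), seed = seedGene(s),
        strategy = searchStrategy(s),
        members = paste(members(s), collapse = ";"),
        signs = paste(ifelse(memberSigns(s) > 0, "+1", "-1"),
                      collapse = ";"),
        parents = paste(ifelse(is.na(memberParents(s)), "-",
                               memberParents(s)), collapse = ";"),
        f_value = fValue(s), size = length(members(s)),
        stringsAsFactors = FALSE))
    summary <- do.call(rbind, rows)
    tsv <- file.path(outDir, "subnetworks.tsv")
    write.table(summary, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in subnetworks) {
        if (length(members(s)) < 2L)
            next
        ed <- data.frame(parent = memberParents(s)[-1L],
                         child = members(s)[-1L], stringsAsFactors = FALSE)
        write.table(ed, file.path(outDir, sprintf("edges_%s_%s.tsv",
                                                  geneSetId(s),
                                                  seedGene(s))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
        software = "netmark",
        version = as.character(packageVersion("netmark")),
        config = if (is.null(config)) NULL else unclass(config),
        activity_rule = "sum(sign_g * z_g) / sqrt(n); signs from Pearson correlation, r >= 0 -> +1",
        sd_convention = "population (divisor N) for z-transformation",
        n_subnetworks = length(subnetworks))
    if (!is.null(inputs))
        manifest$input_md5 <- lapply(inputs, function(p)
            unname(tools::md5sum(p)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(tsv)
}

#' Read back a subnetworks summary TSV
#'
#' Reconstructs the member, sign and parent lists written by
#' \code{\link{writeSubnetworks}}; activity vectors and traces are not
#' stored, so the result is a data frame with list columns rather than
#' \linkS4class{Subnetwork} objects.
#'
#' @param dir a results directory containing \code{subnetworks.tsv}.
#' @return A data frame with columns \code{gene_set_id}, \code{seed},
#'   \code{strategy}, \code{f_value}, \code{size} and list columns
#'   \code{members}, \code{signs}, \code{parents}.
#' @export
readSubnetworks <- function(dir) {
    tsv <- file.path(dir, "subnetworks.tsv")
    if (!file.exists(tsv))
        stop(sprintf("no subnetworks.tsv in %s", dir))
    tab <- read.delim(tsv, stringsAsFactors = FALSE,
                      colClasses = c(members = "character",
                                     signs = "character",
                                     parents = "character"))
    tab$members <- strsplit(tab$members, ";", fixed = TRUE)
    tab$signs <- lapply(strsplit(tab$signs, ";", fixed = TRUE), as.numeric)
    tab$parents <- lapply(strsplit(tab$parents, ";", fixed = TRUE),
                          function(x) ifelse(x == "-", NA_character_, x))
    tab
}
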