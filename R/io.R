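#' Read an LDhat-style per-SNP recombination rate file
#'
#' The expected dialect mirrors the `stats` output of LDhat: a
#' whitespace-separated table with a header line and columns
#' `position  mean_rho  [lower  upper]`. Positions are in kb by default
#' (3 decimals, LDhat convention) and rates are the population-scaled
#' recombination rate rho = 4*Ne*r per kb. On ingest positions become
#' integer bp and rates Morgans/bp; with n positions the file describes
#' n-1 inter-SNP intervals, the rate printed on the last line being
#' ignored (LDhat pads it).
#'
#' @param path file path
#' @param chrom chromosome name to attach (default `"chr1"`)
#' @param population population label (default `NA`)
#' @param positions_unit `"kb"` (default, LDhat) or `"bp"`
#' @param rate_unit `"per_kb"` (default, LDhat) or `"per_bp"`
#' @return a [rate_map()] object; when the file has lower/upper columns
#'   they are kept in attribute `"bounds"`
#' @export
read_ldhat_rates <- function(path, chrom = "chr1", population = NA_character_,
                             positions_unit = c("kb", "bp"),
                             rate_unit = c("per_kb", "per_bp")) {
  positions_unit <- match.arg(positions_unit)
  rate_unit <- match.arg(rate_unit)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) < 2) stop("LDhat rates file needs at least 2 columns")
  pos <- as.numeric(tab[[1]])
  rho <- as.numeric(tab[[2]])
  if (positions_unit == "kb") pos <- pos * 1000
  pos <- round(pos)
  bad <- which(diff(pos) <= 0)
  if (length(bad))
    stop("positions not strictly increasing at line ", bad[1] + 2,
         " of ", path)
  if (any(rho < 0, na.rm = TRUE)) stop("negative recombination rate in ", path)
  if (rate_unit == "per_kb") rho <- rho / 1000
  rm <- rate_map(chrom = chrom, positions = pos,
                 rho = rho[-length(rho)], population = population)
  if (ncol(tab) >= 4) {
    b <- cbind(lower = as.numeric(tab[[3]]), upper = as.numeric(tab[[4]]))
    if (rate_unit == "per_kb") b <- b / 1000
    attr(rm, "bounds") <- b[-nrow(b), , drop = FALSE]
  }
  rm
}

#' Write a rate map in the LDhat-style dialect
#'
#' Inverse of [read_ldhat_rates()] (kb positions, per-kb rates; a padding
#' zero rate is written on the final line).
#'
#' @param ratemap a [rate_map()]
#' @param path output file
#' @export
write_ldhat_rates <- function(ratemap, path) {
  pos_kb <- ratemap$positions / 1000
  rho_kb <- c(ratemap$rho * 1000, 0)
  df <- data.frame(Position = sprintf("%.3f", pos_kb),
                   Mean_rho = sprintf("%.6g", rho_kb))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, sep = "\t")
  invisible(path)
}

#' Read a BED3+ file
#'
#' @param path file path
#' @param layout optional [genome_layout()] for bounds checking
#' @return interval data frame with any of `name`, `score`, `strand`
#'   present in the file
#' @export
read_bed <- function(path, layout = NULL) {
  first <- tryCatch(readLines(path, n = 1), error = function(e) character(0))
  if (length(first) == 0 || !nzchar(first)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(tab) <- cols[seq_len(min(ncol(tab), 6))]
  tab$start <- as.numeric(tab$start); tab$end <- as.numeric(tab$end)
  validate_intervals(tab, layout)
  tab
}

#' Write intervals as BED
#'
#' @param x interval data frame; `name`, `score`, `strand` columns are
#'   written when present
#' @param path output file
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: pad gaps with '.'
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(match(cols, want))
  out <- x[, want[seq_len(3)], drop = FALSE]
  if (upto >= 4) out$name <- if ("name" %in% cols) x$name else "."
  if (upto >= 5) out$score <- if ("score" %in% cols) x$score else "."
  if (upto >= 6) out$strand <- if ("strand" %in% cols) x$strand else "."
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` records and their `exon` children (matched through the
#' `Parent`/`ID` chain via any intermediate mRNA). GFF3 1-based inclusive
#' coordinates become 0-based half-open. Introns are derived as the gaps
#' between consecutive exons within the gene span.
#'
#' @param path GFF3 file
#' @return list with interval data frames `genes` (with `name`, `strand`),
#'   `exons` and `introns` (with `gene` column)
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
    return(list(genes = empty, exons = empty, introns = empty))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("malformed GFF3 line (fewer than 9 fields)")
  m <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    ok <- lengths(regmatches(attrs,
                             gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[ok] <- sub(paste0("^(;)?", key, "="), "",
                   sub(paste0("^.*(^|;)", key, "="), "", attrs[ok]))
    out
  }
  type <- m[, 3]
  df <- data.frame(chrom = m[, 1], type = type,
                   start = as.numeric(m[, 4]) - 1,  # 1-based -> 0-based
                   end = as.numeric(m[, 5]),        # inclusive -> half-open
                   strand = m[, 7],
                   id = attr_field(m[, 9], "ID"),
                   parent = attr_field(m[, 9], "Parent"),
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", , drop = FALSE]
  genes$name <- ifelse(is.na(genes$id), paste0("gene", seq_len(nrow(genes))),
                       genes$id)
  # map any record id to its owning gene id
  owner <- genes$name; names(owner) <- genes$id[!is.na(genes$id)]
  mid <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mid_owner <- owner[mid$parent]; names(mid_owner) <- mid$id
  owner <- c(owner, mid_owner[!is.na(names(mid_owner))])
  exons <- df[df$type == "exon", , drop = FALSE]
  exons$gene <- unname(owner[exons$parent])
  exons <- exons[!is.na(exons$gene), , drop = FALSE]
  for (i in seq_len(nrow(exons))) {
    g <- genes[genes$name == exons$gene[i], ]
    if (nrow(g) == 1 &&
        (exons$start[i] < g$start || exons$end[i] > g$end))
      stop("exon outside its gene span: gene ", exons$gene[i])
  }
  introns <- list()
  for (g in unique(exons$gene)) {
    ex <- exons[exons$gene == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      s <- ex$end[-nrow(ex)]; e <- ex$start[-1]
      keep <- e > s
      if (any(keep))
        introns[[g]] <- data.frame(chrom = ex$chrom[1], start = s[keep],
                                   end = e[keep], gene = g,
                                   stringsAsFactors = FALSE)
    }
  }
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               gene = character(), stringsAsFactors = FALSE)
  rownames(introns) <- NULL
  genes_out <- genes[, c("chrom", "start", "end", "name", "strand")]
  rownames(genes_out) <- NULL
  exons_out <- exons[, c("chrom", "start", "end", "gene", "strand")]
  rownames(exons_out) <- NULL
  list(genes = genes_out, exons = exons_out, introns = introns)
}

#' Write gene models as GFF3
#'
#' @param genes interval data frame with `name` and `strand`
#' @param exons interval data frame with `gene` column mapping to
#'   `genes$name`
#' @param path output file
#' @export
write_gff_genes <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\thotcomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, as.integer(g$start + 1), as.integer(g$end),
                       g$strand, g$name), con)
    ex <- exons[exons$gene == g$name, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\thotcomp\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        ex$chrom[j], as.integer(ex$start[j] + 1), as.integer(ex$end[j]),
        g$strand, g$name, j, g$name), con)
    }
  }
  invisible(path)
}

#' Read a rooted drift tree from a newick file
#'
#' @param path newick file
#' @param populations optional character vector; when given the tip set
#'   must match exactly
#' @return an [ape::read.tree()] `phylo` object with validated branch
#'   lengths
#' @export
read_newick_tree <- function(path, populations = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      any(is.na(tree$edge.length)))
    stop("tree is missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!is.null(populations)) {
    if (!setequal(tree$tip.label, populations))
      stop("tree tips do not match population names; tree-only: ",
           paste(setdiff(tree$tip.label, populations), collapse = ","),
           "; metadata-only: ",
           paste(setdiff(populations, tree$tip.label), collapse = ","))
  }
  tree
}

#' Read a genome layout TSV (chrom, length)
#' @param path TSV with two columns and a header
#' @return a [genome_layout()]
#' @export
read_genome_layout <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  genome_layout(stats::setNames(as.numeric(tab[[2]]), tab[[1]]))
}

#' Write a genome layout TSV
#' @param layout a [genome_layout()]
#' @param path output file
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(data.frame(chrom = names(layout),
                                length = as.numeric(layout)),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read population metadata (name, Ne, F, sample size)
#' @param path TSV with header `population Ne F n`
#' @return data frame, validated
#' @export
read_population_meta <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("population", "Ne", "F", "n")
  if (any(tab$Ne <= 0)) stop("Ne must be positive")
  if (any(tab$F < 0 | tab$F > 1)) stop("inbreeding F must be in [0,1]")
  if (any(tab$n < 1)) stop("sample size must be >= 1")
  tab
}

#' Read a symmetric population matrix TSV (e.g. pairwise F_ST)
#' @param path TSV with row and column population headers
#' @return numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Write a population matrix TSV
#' @param m numeric matrix with dimnames
#' @param path output file
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(population = rownames(m), m,
                                check.names = FALSE),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a homozygosity-frequency table (populations x mutations)
#' @param path TSV, first column population names
#' @return numeric matrix, rows = populations
#' @export
read_genotype_freq_table <- function(path) {
  m <- read_matrix_tsv(path)
  if (any(m < 0 | m > 1)) stop("homozygosity frequencies must lie in [0,1]")
  m
}
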