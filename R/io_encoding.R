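#' Site maps: per-SNP allele dictionaries
#'
#' A site map records, for each SNP index `1..l`, the chromosome, genomic
#' position and the two alleles of the bi-allelic site (the common "wild"
#' allele coded +1 and the "rare" allele coded -1).  It is what lets the
#' package translate between nucleotides and the numeric +1/-1 coding used
#' by the completion machinery.
#'
#' @param chrom character vector of chromosome labels
#' @param pos integer vector of genomic positions (bp)
#' @param wild,rare single-character vectors of alleles in A/C/G/T
#' @return a data frame of class `site_map` with columns
#'   `index`, `chrom`, `pos`, `wild`, `rare`
#' @export
site_map <- function(chrom, pos, wild, rare) {
  l <- length(wild)
  stopifnot(length(rare) == l, length(pos) == l)
  chrom <- rep_len(as.character(chrom), l)
  wild <- toupper(wild); rare <- toupper(rare)
  if (!all(wild %in% c("A", "C", "G", "T")) || !all(rare %in% c("A", "C", "G", "T")))
    stop("alleles must be A, C, G or T")
  if (any(wild == rare))
    stop("wild and rare alleles must differ at every site (bi-allelic assumption)")
  structure(data.frame(index = seq_len(l), chrom = chrom, pos = as.integer(pos),
                       wild = wild, rare = rare, stringsAsFactors = FALSE),
            class = c("site_map", "data.frame"))
}

#' Read a site map from a TSV file
#'
#' Expected columns: `index` (1-based, contiguous), `chrom`, `pos`, `wild`,
#' `rare`.
#'
#' @param file path or connection
#' @return a [site_map]
#' @export
read_site_map <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("index", "chrom", "pos", "wild", "rare")
  if (!all(need %in% names(d)))
    stop("site map must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$index), ]
  if (!identical(as.integer(d$index), seq_len(nrow(d))))
    stop("site map indices must be contiguous 1..l")
  site_map(d$chrom, d$pos, d$wild, d$rare)
}

#' Encode nucleotide observations as +1/-1
#'
#' Maps a base at a bi-allelic site to its numeric code: the wild allele
#' becomes +1 and the rare allele -1.  A base matching neither allele is a
#' non-biallelic observation; by default it is an error, optionally it is
#' dropped (coded `NA`).
#'
#' @param base character vector of observed bases
#' @param wild,rare the site's alleles (recycled)
#' @param on_mismatch `"error"` (default) or `"drop"` (return `NA`)
#' @return numeric vector of +1 / -1 (and `NA` under `"drop"`)
#' @examples
#' encode_allele(c("A", "G"), wild = "G", rare = "A")   # -1, +1
#' @export
encode_allele <- function(base, wild, rare, on_mismatch = c("error", "drop")) {
  on_mismatch <- match.arg(on_mismatch)
  base <- toupper(base)
  n <- length(base)
  wild <- rep_len(toupper(wild), n); rare <- rep_len(toupper(rare), n)
  code <- ifelse(base == wild, 1, ifelse(base == rare, -1, NA_real_))
  if (anyNA(code) && on_mismatch == "error")
    stop("non-biallelic observation: base ", base[which(is.na(code))[1]],
         " matches neither allele at its site")
  code
}

#' Encode a haplotype nucleotide sequence against a site map
#'
#' The inverse of [decode_haplotype()]: wild allele -> +1, rare -> -1,
#' `"-"` -> `NA`.
#'
#' @param seq a single string, or character vector of per-site bases
#' @param map a [site_map]
#' @param on_mismatch passed to [encode_allele()]
#' @return numeric vector over \{+1, -1, NA\}
#' @export
encode_haplotype <- function(seq, map, on_mismatch = c("error", "drop")) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "")[[1]]
  if (length(seq) != nrow(map))
    stop("sequence length does not match the site map")
  out <- rep(NA_real_, length(seq))
  filled <- seq != "-"
  out[filled] <- encode_allele(seq[filled], map$wild[filled], map$rare[filled],
                               on_mismatch)
  out
}

#' Decode a +1/-1 haplotype vector to nucleotides
#'
#' +1 maps to the wild allele, -1 to the rare allele and `NA` (an
#' unphased site) to `"-"`.
#'
#' @param hap numeric vector over \{+1, -1, NA\}
#' @param map a [site_map] of matching length
#' @return a single nucleotide string
#' @export
decode_haplotype <- function(hap, map) {
  if (length(hap) != nrow(map))
    stop("haplotype length does not match the site map")
  out <- ifelse(is.na(hap), "-", ifelse(hap > 0, map$wild, map$rare))
  paste0(out, collapse = "")
}

#' Fragments: per-read SNP observations
#'
#' A fragment is one read's SNP-level content: a read id plus parallel
#' vectors of covered SNP indices (1-based, strictly increasing) and coded
#' alleles (+1/-1).
#'
#' @param id read identifier
#' @param sites integer vector of SNP indices
#' @param alleles numeric vector over \{+1, -1\}
#' @return a list of class `fragment`
#' @export
fragment <- function(id, sites, alleles) {
  sites <- as.integer(sites)
  if (length(sites) < 1L) stop("a fragment must cover at least one site")
  if (length(sites) != length(alleles)) stop("sites/alleles length mismatch")
  if (is.unsorted(sites, strictly = TRUE))
    stop("fragment SNP indices must be strictly increasing")
  if (!all(alleles %in% c(-1, 1))) stop("fragment alleles must be +1 or -1")
  structure(list(id = as.character(id), sites = sites, alleles = as.numeric(alleles)),
            class = "fragment")
}

#' Parse a fragment file
#'
#' Two dialects are supported.
#'
#' * `"hapcut"`: the whitespace fragment format used by HapCUT-family
#'   tools.  Each line is one read:
#'   `<n_segments> <read_id> <start_1> <alleles_1> ... <start_k> <alleles_k> <quality>`
#'   where each `alleles` string is over `0` (wild, coded +1) and `1`
#'   (rare, coded -1) and `start` is the 1-based index of its first SNP.
#'   The quality string is parsed for well-formedness but unused (the
#'   completion model is unweighted).
#' * `"triplet"`: a headerless whitespace/TSV table with columns
#'   `read_id`, `snp_index`, `code` (+1/-1); rows of one read need not be
#'   adjacent.
#'
#' @param file path or connection
#' @param dialect `"hapcut"` or `"triplet"`
#' @return list of [fragment] objects (empty fragments are skipped with a
#'   warning; malformed lines are an error naming the line number)
#' @export
parse_fragments <- function(file, dialect = c("hapcut", "triplet")) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) return(list())
  if (dialect == "hapcut") {
    frags <- vector("list", length(lines_keep))
    for (k in seq_along(lines_keep)) {
      ln <- lines_keep[k]
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      nseg <- suppressWarnings(as.integer(tok[1]))
      if (is.na(nseg) || length(tok) != 2L + 2L * nseg + 1L)
        stop(sprintf("malformed fragment line %d: expected %s segment blocks",
                     ln, tok[1]))
      sites <- integer(0); alleles <- numeric(0)
      for (s in seq_len(nseg)) {
        start <- suppressWarnings(as.integer(tok[2L * s + 1L]))
        astr <- tok[2L * s + 2L]
        if (is.na(start) || !grepl("^[01]+$", astr))
          stop(sprintf("malformed fragment line %d: bad segment %d", ln, s))
        a <- as.integer(strsplit(astr, "")[[1]])
        sites <- c(sites, start + seq_along(a) - 1L)
        alleles <- c(alleles, ifelse(a == 0L, 1, -1))
      }
      qual <- tok[length(tok)]
      if (nchar(qual) != length(sites))
        stop(sprintf("malformed fragment line %d: quality string length %d, expected %d",
                     ln, nchar(qual), length(sites)))
      if (is.unsorted(sites, strictly = TRUE))
        stop(sprintf("malformed fragment line %d: overlapping or unordered segments", ln))
      frags[[k]] <- fragment(tok[2], sites, alleles)
    }
    frags
  } else {
    d <- utils::read.table(text = lines[lines_keep], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("read_id", "snp_index", "code"))
    if (!all(d$code %in% c(-1, 1))) stop("triplet codes must be +1 or -1")
    ids <- unique(d$read_id)
    out <- lapply(ids, function(id) {
      sub <- d[d$read_id == id, ]
      sub <- sub[order(sub$snp_index), ]
      if (anyDuplicated(sub$snp_index))
        sub <- stats::aggregate(code ~ snp_index, data = sub,
                                FUN = function(v) if (length(unique(v)) == 1) v[1] else NA)
      if (anyNA(sub$code)) {
        warning("conflicting duplicate triplet observations dropped for read ", id)
        sub <- sub[!is.na(sub$code), ]
      }
      if (!nrow(sub)) return(NULL)
      fragment(id, sub$snp_index, sub$code)
    })
    out[!vapply(out, is.null, logical(1))]
  }
}

#' Write fragments in a fragment-file dialect
#'
#' Inverse of [parse_fragments()]; used by the simulator and for
#' round-tripping.  In the hapcut dialect, runs of consecutive SNP indices
#' become segments and a constant dummy quality (`"~"`) is emitted.
#'
#' @param fragments list of [fragment]
#' @param file path or connection
#' @param dialect `"hapcut"` or `"triplet"`
#' @export
write_fragments <- function(fragments, file, dialect = c("hapcut", "triplet")) {
  dialect <- match.arg(dialect)
  if (dialect == "hapcut") {
    lines <- vapply(fragments, function(f) {
      brk <- c(0L, which(diff(f$sites) != 1L), length(f$sites))
      segs <- character(0)
      for (s in seq_len(length(brk) - 1L)) {
        idx <- (brk[s] + 1L):brk[s + 1L]
        segs <- c(segs, as.character(f$sites[idx[1]]),
                  paste0(ifelse(f$alleles[idx] > 0, "0", "1"), collapse = ""))
      }
      paste(c(length(brk) - 1L, f$id, segs,
              strrep("~", length(f$sites))), collapse = " ")
    }, character(1))
    writeLines(lines, file)
  } else {
    d <- do.call(rbind, lapply(fragments, function(f)
      data.frame(read_id = f$id, snp_index = f$sites, code = f$alleles)))
    utils::write.table(d, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Build the read matrix from fragments
#'
#' Each fragment becomes one row; its coded alleles are placed at its
#' covered columns and every other cell is an unobserved (structural) zero.
#' If a cell is observed more than once within a row, the majority code
#' wins and exact ties are dropped from Omega.  Reads whose observations
#' all cancel are dropped with a warning.
#'
#' @param fragments list of [fragment]
#' @param l haplotype length (number of SNP columns); every fragment site
#'   must be `<= l`
#' @return a [read_matrix]; the attribute `"read_ids"` carries the row ids
#' @export
build_read_matrix <- function(fragments, l) {
  l <- as.integer(l)
  if (!length(fragments)) {
    return(read_matrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(0L, l))))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ids <- character(length(fragments))
  for (k in seq_along(fragments)) {
    f <- fragments[[k]]
    if (any(f$sites > l))
      stop("fragment ", f$id, " covers SNP index ", max(f$sites),
           " beyond haplotype length l = ", l)
    ii <- c(ii, rep.int(k, length(f$sites)))
    jj <- c(jj, f$sites)
    xx <- c(xx, f$alleles)
    ids[k] <- f$id
  }
  # majority vote per cell; sparseMatrix sums duplicates, sign() resolves,
  # exact ties sum to zero and fall out of Omega via drop0
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(fragments), l))
  m@x <- sign(m@x)
  m <- Matrix::drop0(m)
  keep <- tabulate(m@i + 1L, nbins = nrow(m)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " read(s) with no surviving observations dropped")
    m <- m[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  out <- read_matrix(m)
  attr(out, "read_ids") <- ids
  out
}

#' Write phased haplotype blocks in a HapCUT-style text format
#'
#' One section per block, ordered by first SNP index:
#' ```
#' BLOCK: offset <first SNP> len <SNP span> phased <n phased>
#' <index> <allele1> <allele2> <chrom> <pos>
#' ...
#' ********
#' ```
#' Alleles are written as `0` (wild, +1), `1` (rare, -1) or `-` (unphased);
#' unphased sites are excluded from the `phased` count.  Without a site
#' map, chromosome and position are written as `.` and the SNP index.
#'
#' @param phasing a `hap_phasing` result from [hap_assemble()]
#' @param map optional [site_map]
#' @param file path or connection
#' @export
write_phased_blocks <- function(phasing, map = NULL, file) {
  code_chr <- function(v) ifelse(is.na(v), "-", ifelse(v > 0, "0", "1"))
  blocks <- phasing$blocks
  if (length(blocks)) {
    ord <- order(vapply(blocks, function(b) b$sites[1], numeric(1)))
    blocks <- blocks[ord]
  }
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  for (b in blocks) {
    h1 <- b$pair$h1; h2 <- b$pair$h2
    phased <- sum(!is.na(h1) & !is.na(h2))
    span <- b$sites[length(b$sites)] - b$sites[1] + 1L
    writeLines(sprintf("BLOCK: offset %d len %d phased %d",
                       b$sites[1], span, phased), con)
    for (k in seq_along(b$sites)) {
      j <- b$sites[k]
      chrom <- if (!is.null(map)) map$chrom[j] else "."
      pos <- if (!is.null(map)) map$pos[j] else j
      writeLines(sprintf("%d\t%s\t%s\t%s\t%s", j,
                         code_chr(h1[k]), code_chr(h2[k]), chrom, pos), con)
    }
    writeLines("********", con)
  }
  invisible(NULL)
}

#' Read a phased-block file written by [write_phased_blocks()]
#'
#' @param file path or connection
#' @param l haplotype length; defaults to the largest SNP index present
#' @return a list with `h1`, `h2` (length-`l` vectors over \{+1,-1,NA\})
#'   and `blocks` (list of per-block site index vectors)
#' @export
read_phased_blocks <- function(file, l = NULL) {
  lines <- readLines(file)
  decode <- function(ch) ifelse(ch == "-", NA_real_, ifelse(ch == "0", 1, -1))
  sites <- integer(0); a1 <- numeric(0); a2 <- numeric(0)
  blocks <- list(); cur <- integer(0)
  for (ln in lines) {
    if (startsWith(ln, "BLOCK:")) {
      if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- integer(0)
    } else if (startsWith(ln, "****")) {
      if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- integer(0)
    } else if (nzchar(trimws(ln))) {
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      j <- as.integer(tok[1])
      sites <- c(sites, j); cur <- c(cur, j)
      a1 <- c(a1, decode(tok[2])); a2 <- c(a2, decode(tok[3]))
    }
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (is.null(l)) l <- if (length(sites)) max(sites) else 0L
  h1 <- rep(NA_real_, l); h2 <- rep(NA_real_, l)
  h1[sites] <- a1; h2[sites] <- a2
  list(h1 = h1, h2 = h2, blocks = blocks)
}

#' Read a truth haplotype table
#'
#' TSV with columns `index`, `h1`, `h2` (values +1/-1, or NA).
#'
#' @param file path or connection
#' @param l haplotype length; defaults to the largest index
#' @return a [haplotype_pair]
#' @export
read_truth_haplotypes <- function(file, l = NULL) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  if (is.null(l)) l <- max(d$index)
  h1 <- rep(NA_real_, l); h2 <- rep(NA_real_, l)
  h1[d$index] <- d$h1; h2[d$index] <- d$h2
  haplotype_pair(h1, h2)
}

#' Write a truth haplotype table (TSV: index, h1, h2)
#' @param pair a [haplotype_pair]
#' @param file path or connection
#' @export
write_truth_haplotypes <- function(pair, file) {
  d <- data.frame(index = seq_along(pair$h1), h1 = pair$h1, h2 = pair$h2)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
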