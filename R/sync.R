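#' Write pooled counts in sync format
#'
#' Writes the tab-separated pooled-count format popularized by PoPoolation2:
#' chromosome, 1-based position, reference base, then one "A:T:C:G:N:del"
#' count string per pool.
#'
#' @param x a \code{sync_set} (see \code{\link{pool_genome}}) or a list with
#'   \code{sites} (chrom, pos, ref) and \code{counts} (list of sites x 6
#'   matrices).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(is.list(x$counts), !is.null(x$sites))
  cols <- vapply(x$counts, function(m)
    apply(m[, SYNC_BASES, drop = FALSE], 1L, paste, collapse = ":"),
    character(nrow(x$sites)))
  df <- cbind(data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                         ref = x$sites$ref), as.data.frame(cols))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sync file
#'
#' @param path sync file path.
#' @param pool_names optional pool names (default pool1, pool2, ...).
#' @return a \code{sync_set}: \code{sites} (chrom, pos, ref) and
#'   \code{counts}, a named list of sites x 6 integer matrices with columns
#'   A, T, C, G, N, del.  Positions must be strictly increasing within each
#'   chromosome.
#' @export
read_sync <- function(path, pool_names = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 4L) stop("sync file needs at least one pool column")
  sites <- data.frame(chrom = raw[[1L]], pos = as.integer(raw[[2L]]),
                      ref = raw[[3L]])
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  n_pools <- ncol(raw) - 3L
  pool_names <- pool_names %||% paste0("pool", seq_len(n_pools))
  counts <- lapply(seq_len(n_pools), function(k) {
    parts <- strsplit(raw[[3L + k]], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) stop("malformed count string in pool ", k)
    m <- matrix(as.integer(unlist(parts)), ncol = 6L, byrow = TRUE)
    if (any(m < 0)) stop("negative counts in pool ", k)
    colnames(m) <- SYNC_BASES
    m
  })
  names(counts) <- pool_names
  structure(list(sites = sites, counts = counts), class = "sync_set")
}
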