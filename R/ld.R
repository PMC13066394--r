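# LD abstraction: pairwise r2 lookups without an external reference panel.

#' Construct an LD provider
#'
#' An `ld_provider` answers pairwise r-squared queries between variants.
#' It wraps either a square r2 matrix (ids as dimnames) or a block
#' assignment (all pairs within a block share one r2, cross-block pairs are
#' 0). Unknown pairs and cross-chromosome pairs return 0; `r2(v, v)` is
#' always 1.
#'
#' @param r2_matrix Optional square symmetric matrix with variant ids as
#'   dimnames.
#' @param blocks Optional named integer/character vector: variant id ->
#'   block label.
#' @param within_r2 r2 assigned to distinct variants sharing a block
#'   (default 1, i.e. perfect proxies).
#' @param chrom Optional named character vector, variant id -> chromosome,
#'   used to force cross-chromosome r2 to 0.
#' @return An object of class `ld_provider` with a `$r2(id_a, id_b)` method.
#' @export
ld_provider <- function(r2_matrix = NULL, blocks = NULL, within_r2 = 1,
                        chrom = NULL) {
  if (is.null(r2_matrix) && is.null(blocks)) {
    stop("ld_provider: supply r2_matrix or blocks", call. = FALSE)
  }
  if (!is.null(r2_matrix)) {
    if (is.null(rownames(r2_matrix)) || is.null(colnames(r2_matrix))) {
      stop("ld_provider: r2_matrix needs variant ids as dimnames",
           call. = FALSE)
    }
    if (max(abs(r2_matrix - t(r2_matrix))) > 1e-8) {
      stop("ld_provider: r2_matrix must be symmetric", call. = FALSE)
    }
  }
  r2_fun <- function(id_a, id_b) {
    n <- max(length(id_a), length(id_b))
    id_a <- rep_len(as.character(id_a), n)
    id_b <- rep_len(as.character(id_b), n)
    out <- numeric(n)
    same <- id_a == id_b
    out[same] <- 1
    idx <- which(!same)
    if (length(idx) > 0) {
      if (!is.null(r2_matrix)) {
        known <- id_a[idx] %in% rownames(r2_matrix) &
          id_b[idx] %in% colnames(r2_matrix)
        out[idx[known]] <- r2_matrix[cbind(id_a[idx[known]], id_b[idx[known]])]
      } else {
        ba <- blocks[id_a[idx]]
        bb <- blocks[id_b[idx]]
        hit <- !is.na(ba) & !is.na(bb) & ba == bb
        out[idx[hit]] <- within_r2
      }
    }
    if (!is.null(chrom)) {
      ca <- chrom[id_a]
      cb <- chrom[id_b]
      cross <- !same & !is.na(ca) & !is.na(cb) & ca != cb
      out[cross] <- 0
    }
    pmin(pmax(out, 0), 1)
  }
  structure(list(r2 = r2_fun), class = "ld_provider")
}

#' Load an LD provider from a square r2 matrix file
#'
#' Expects a tab-separated file whose header and first column carry variant
#' ids.
#'
#' @param path TSV file path.
#' @return An `ld_provider`.
#' @export
read_ld_matrix <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_provider(r2_matrix = m)
}

#' Write an LD provider's matrix for a set of variant ids
#'
#' @param ld An `ld_provider`.
#' @param ids Variant ids to materialize.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, ids, path) {
  m <- outer(ids, ids, function(a, b) ld$r2(a, b))
  dimnames(m) <- list(ids, ids)
  out <- data.frame(id = ids, m, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
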