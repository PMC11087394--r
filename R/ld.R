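## LD matrices of squared correlations, used only for clumping.

#' Construct an LD matrix of squared correlations
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param ids variant identifiers, one per row/column of `r2`.
#' @param positions optional base-pair positions aligned to `ids`.
#' @param tol asymmetry tolerance.
#' @return Object of class `ld_matrix`: list with `ids`, `r2`, `positions`.
#' @export
ld_matrix <- function(r2, ids, positions = NULL, tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix is not square")
  if (length(ids) != nrow(r2)) stop("id list length does not match matrix dimension")
  if (anyDuplicated(ids)) stop("duplicated ids in LD matrix")
  if (any(is.na(r2))) stop("missing values in LD matrix")
  if (any(r2 < 0 | r2 > 1)) stop("r2 out of range [0,1]")
  if (max(abs(r2 - t(r2))) > tol) stop("LD matrix not symmetric within tolerance")
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  if (!is.null(positions) && length(positions) != length(ids))
    stop("positions length does not match ids")
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = as.character(ids), r2 = r2, positions = positions),
            class = "ld_matrix")
}

#' Read an LD matrix from disk
#'
#' Two layouts are supported: a dense tab-delimited square matrix plus a
#' one-column id file (`ids` given), or a long-format file with header
#' `id1 id2 r2` (`ids = NULL`); unlisted long-format pairs default to 0.
#'
#' @param path matrix file (dense) or long-format file.
#' @param ids path to a one-column id file for the dense layout, or NULL.
#' @param positions optional positions aligned to the ids.
#' @return An [ld_matrix] object.
#' @export
load_ld <- function(path, ids = NULL, positions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(ids)) {
    long <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id1", "id2", "r2")
    if (!all(need %in% names(long)))
      stop("long-format LD file needs columns id1, id2, r2")
    uid <- sort(unique(c(long$id1, long$id2)))
    m <- matrix(0, length(uid), length(uid), dimnames = list(uid, uid))
    m[cbind(long$id1, long$id2)] <- long$r2
    m[cbind(long$id2, long$id1)] <- long$r2
    diag(m) <- 1
    ld_matrix(m, uid, positions)
  } else {
    idv <- readLines(ids)
    idv <- idv[nzchar(idv)]
    m <- as.matrix(read.delim(path, header = FALSE))
    if (nrow(m) != length(idv))
      stop("id count (", length(idv), ") does not match matrix rows (", nrow(m), ")")
    ld_matrix(m, idv, positions)
  }
}

## r2 lookup for a pair set; ids absent from the matrix count as uncorrelated.
ld_r2 <- function(ld, id_a, ids_b) {
  out <- numeric(length(ids_b))
  if (!(id_a %in% ld$ids)) return(out)
  present <- ids_b %in% ld$ids
  out[present] <- ld$r2[id_a, ids_b[present]]
  out
}
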