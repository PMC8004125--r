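#' Paired-modality patch collections
#'
#' A `paired_patches` object holds co-registered B-mode and CEUS patches with
#' their class labels and provenance. Patches are stored as two
#' `size x size x n` arrays of 8-bit gray levels (0--255), one per modality,
#' plus a label factor with levels `HCC` (hepatocellular carcinoma, the
#' positive class) and `PAR` (cirrhotic parenchyma, the negative class).
#'
#' @param bmode,ceus `size x size x n` numeric arrays (a single `size x size`
#'   matrix is promoted to `n = 1`).
#' @param label character or factor of length `n` with values `"HCC"`/`"PAR"`.
#' @param origin optional data frame with columns `frame_id`, `row`, `col`
#'   (0-based top-left corner of each patch in its source frame).
#' @param augmentation character vector of augmentation tags
#'   (`none`, `rot90`, `rot180`, `rot270`, `flip_h`, `flip_v`, `translate`).
#' @return an object of class `paired_patches`.
#' @export
paired_patches <- function(bmode, ceus, label, origin = NULL,
                           augmentation = NULL) {
  if (is.matrix(bmode)) bmode <- array(bmode, c(dim(bmode), 1L))
  if (is.matrix(ceus)) ceus <- array(ceus, c(dim(ceus), 1L))
  stopifnot(length(dim(bmode)) == 3L, length(dim(ceus)) == 3L)
  if (!identical(dim(bmode), dim(ceus)))
    stopf("bmode and ceus arrays must have identical dimensions")
  if (dim(bmode)[1] != dim(bmode)[2])
    stopf("patches must be square")
  n <- dim(bmode)[3]
  label <- factor(as.character(label), levels = c("HCC", "PAR"))
  if (length(label) != n || anyNA(label))
    stopf("label must be length %d with values 'HCC' or 'PAR'", n)
  if (is.null(augmentation)) augmentation <- rep("none", n)
  structure(list(bmode = bmode, ceus = ceus, label = label,
                 origin = origin, augmentation = augmentation),
            class = "paired_patches")
}

#' @export
length.paired_patches <- function(x) dim(x$bmode)[3]

#' @export
`[.paired_patches` <- function(x, i) {
  out <- paired_patches(x$bmode[, , i, drop = FALSE], x$ceus[, , i, drop = FALSE],
                        x$label[i],
                        if (!is.null(x$origin)) x$origin[i, , drop = FALSE],
                        x$augmentation[i])
  if (!is.null(x$fused)) {
    out$fused <- x$fused[, , i, drop = FALSE]
    out$fuse_spec <- x$fuse_spec
  }
  out
}

#' @export
c.paired_patches <- function(...) {
  xs <- list(...)
  p <- dim(xs[[1]]$bmode)[1]
  bm <- array(unlist(lapply(xs, function(x) x$bmode)), c(p, p, sum(vapply(xs, length, 1L))))
  ce <- array(unlist(lapply(xs, function(x) x$ceus)), dim(bm))
  org <- if (all(vapply(xs, function(x) !is.null(x$origin), TRUE)))
    do.call(rbind, lapply(xs, function(x) x$origin))
  paired_patches(bm, ce,
                 unlist(lapply(xs, function(x) as.character(x$label))),
                 org,
                 unlist(lapply(xs, function(x) x$augmentation)))
}

#' @export
print.paired_patches <- function(x, ...) {
  p <- dim(x$bmode)[1]
  cat(sprintf("<paired_patches> %d patch pair(s), %dx%d px\n", length(x), p, p))
  print(table(label = x$label))
  invisible(x)
}
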