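new_gram_block <- function(site_i, site_j, block, n_rows) {
  structure(list(site_i = site_i, site_j = site_j,
                 block = as.matrix(block), n_rows = as.integer(n_rows)),
            class = "gram_block")
}

#' @export
print.gram_block <- function(x, ...) {
  cat(sprintf("<gram_block> X[%s]' X[%s]: %d x %d over %d rows\n",
              x$site_i, x$site_j, nrow(x$block), ncol(x$block), x$n_rows))
  invisible(x)
}

#' Site-local Gram block
#'
#' Computes a site's own cross-product block `X_k' X_k` over the named local
#' columns — the site-specific component of the global covariance matrix.
#' This is summary-level: only the p_k x p_k block leaves the site.
#'
#' @param partition a `site_partition`.
#' @param columns ordered column names to include (default: all local columns).
#' @param weights optional nonnegative row weights; the block is then
#'   `X_k' diag(w) X_k`.
#' @return a `gram_block` with `site_i == site_j`.
#' @export
gram_self <- function(partition, columns = NULL, weights = NULL) {
  columns <- columns %||% names(partition$data)
  if (!length(columns))
    vdra_error("vdra_spec_error", "gram_self needs at least one column")
  X <- partition_matrix(partition, columns)
  if (!is.null(weights)) {
    check_weights(weights, nrow(X))
    X <- X * sqrt(weights)
  }
  new_gram_block(partition$site_id, partition$site_id, crossprod(X), nrow(X))
}

check_weights <- function(w, n) {
  if (length(w) != n)
    vdra_error("vdra_domain_error", "weights must have one entry per row")
  if (any(w < 0) || anyNA(w))
    vdra_error("vdra_domain_error", "weights must be nonnegative")
  invisible(TRUE)
}

#' Random orthonormal mask basis in the complement of a site's column space
#'
#' Draws an n x g Gaussian matrix, projects out the site's local column
#' space, and orthonormalizes, yielding Z with `Z'Z = I` and `Z'X_local = 0`
#' (both within 1e-10). Z spans a random g-dimensional subspace of the
#' orthogonal complement of the local columns, so `(I - ZZ')X_b` masks
#' another site's columns without disturbing cross-products with this site.
#'
#' @param partition masking site's `site_partition`.
#' @param g mask dimension, `1 <= g <= n - p_local` (g = 0 disables masking).
#' @param seed integer seed; the basis is deterministic given it.
#' @param columns local columns whose span is projected out (default: all).
#' @param weights optional nonnegative row weights; the complement is taken
#'   with respect to the sqrt(w)-scaled columns.
#' @return an object of class `mask_basis` with elements `owner_site`, `Z`, `g`.
#' @export
make_mask_basis <- function(partition, g = NULL, seed = 1L, columns = NULL,
                            weights = NULL) {
  X <- partition_matrix(partition, columns)
  if (!is.null(weights)) {
    check_weights(weights, nrow(X))
    X <- X * sqrt(weights)
  }
  n <- nrow(X); p <- ncol(X)
  g <- g %||% ((n - p) %/% 2L)
  if (g > n - p)
    vdra_error("vdra_dimension_error",
      sprintf("mask dimension g = %d exceeds n - p = %d", g, n - p))
  if (g < 0L) vdra_error("vdra_dimension_error", "g must be nonnegative")
  if (g == 0L) {
    Z <- matrix(numeric(0), n, 0L)
  } else {
    set.seed(child_seed(seed, "mask", partition$site_id))
    G0 <- matrix(rnorm(n * g), n, g)
    qx <- qr(X)
    R1 <- qr.resid(qx, G0)          # project out col(X)
    Z <- qr.Q(qr(R1))[, seq_len(g), drop = FALSE]
    Z <- qr.resid(qx, Z)            # second pass: Z'X down to ~1e-13
  }
  structure(list(owner_site = partition$site_id, Z = Z, g = g),
            class = "mask_basis")
}

# apply the masking operator (I - ZZ') to another site's columns
mask_columns <- function(basis, X) {
  if (basis$g == 0L) M <- X
  else M <- X - basis$Z %*% crossprod(basis$Z, X)
  structure(list(producer_site = NA_character_, matrix = M,
                 provenance = sprintf("masked by site '%s' basis (g = %d)",
                                      basis$owner_site, basis$g)),
            class = "masked_payload")
}

#' Secure cross-site cross-product (sequential masking protocol)
#'
#' Computes the off-diagonal block `X_a' X_b` of the global covariance matrix
#' between two sites without either revealing its patient-level columns. The
#' protocol is sequential: site A sends its mask basis Z (n x g, orthogonal
#' complement of A's columns) to site B; B returns the masked projection
#' `(I - ZZ')X_b` (n x p_b); A computes `X_a'(I - ZZ')X_b = X_a'X_b` since
#' `Z'X_a = 0`. A never sees raw `X_b`, B never sees raw `X_a`.
#'
#' When a `network` is supplied, both messages travel as CSV+sidecar files
#' through the audited transfer fabric (routed hub-and-spoke or direct per
#' the network's mode); otherwise they are exchanged in memory.
#'
#' @param site_a,site_b row-aligned `site_partition`s; A runs the mask.
#' @param g mask dimension (default `floor((n - p_a)/2)`); `g = 0` disables
#'   masking (degenerate, payload equals raw).
#' @param seed integer seed for the mask basis.
#' @param columns_a,columns_b column orders at each site (default: all).
#' @param weights optional nonnegative row weights `w`; the result is then
#'   `X_a' diag(w) X_b`, obtained by running the protocol on sqrt(w)-scaled
#'   columns.
#' @param network optional `vdra_network` carrying the protocol files.
#' @param materialize_full_operator if `TRUE`, B receives the full n x n
#'   operator `I - ZZ'` instead of Z — the payload-size regime where transfer
#'   cost scales with n x n; intended for transfer-metrics experiments only.
#' @param label payload name stem used for files on the network.
#' @return a `gram_block` for (site_a, site_b). Attributes: `payload` (the
#'   `masked_payload` B produced, for leakage auditing) and `transcript`
#'   (the ordered message list).
#' @export
secure_cross_product <- function(site_a, site_b, g = NULL, seed = 1L,
                                 columns_a = NULL, columns_b = NULL,
                                 weights = NULL, network = NULL,
                                 materialize_full_operator = FALSE,
                                 label = "xprod") {
  check_row_alignment(list(site_a, site_b))
  Xa <- partition_matrix(site_a, columns_a)
  Xb <- partition_matrix(site_b, columns_b)
  if (!is.null(weights)) {
    check_weights(weights, nrow(Xa))
    Xa <- Xa * sqrt(weights)
    Xb <- Xb * sqrt(weights)
  }
  basis <- make_mask_basis(site_a, g = g, seed = seed, columns = columns_a,
                           weights = weights)
  transcript <- list()

  # message 1, A -> B: the mask (Z, or the full n x n operator)
  m1 <- if (materialize_full_operator)
    diag(nrow(Xa)) - tcrossprod(basis$Z) else basis$Z
  if (!is.null(network)) {
    files <- write_payload(m1, outbox(network, site_a$site_id),
                           paste0(label, "-mask"), site_a$site_id,
                           if (materialize_full_operator) "mask-operator" else "mask-basis")
    route(network, site_a$site_id, site_b$site_id, files)
    rp <- read_payload(inbox(network, site_b$site_id), paste0(label, "-mask"))
    m1 <- rp$matrix
  }
  transcript[[1L]] <- list(from = site_a$site_id, to = site_b$site_id,
                           kind = "mask")

  # site B masks its columns and replies
  payload <- if (materialize_full_operator) {
    structure(list(producer_site = site_b$site_id, matrix = m1 %*% Xb,
                   provenance = sprintf("masked by site '%s' operator",
                                        site_a$site_id)),
              class = "masked_payload")
  } else {
    p <- mask_columns(list(owner_site = site_a$site_id, Z = m1,
                           g = ncol(m1)), Xb)
    p$producer_site <- site_b$site_id
    p
  }

  # message 2, B -> A: the masked projection (n x p_b)
  M <- payload$matrix
  if (!is.null(network)) {
    files <- write_payload(M, outbox(network, site_b$site_id),
                           paste0(label, "-masked"), site_b$site_id, "masked-columns")
    route(network, site_b$site_id, site_a$site_id, files)
    rp <- read_payload(inbox(network, site_a$site_id), paste0(label, "-masked"))
    M <- rp$matrix
  }
  transcript[[2L]] <- list(from = site_b$site_id, to = site_a$site_id,
                           kind = "masked-columns")

  blk <- crossprod(Xa, M)
  dimnames(blk) <- list(colnames(Xa), colnames(Xb))
  out <- new_gram_block(site_a$site_id, site_b$site_id, blk, nrow(Xa))
  attr(out, "payload") <- payload
  attr(out, "transcript") <- transcript
  out
}

#' @rdname secure_cross_product
#' @export
secure_cross_product_weighted <- function(site_a, site_b, weights, g = NULL,
                                          seed = 1L, columns_a = NULL,
                                          columns_b = NULL, network = NULL,
                                          label = "xprodw") {
  secure_cross_product(site_a, site_b, g = g, seed = seed,
                       columns_a = columns_a, columns_b = columns_b,
                       weights = weights, network = network, label = label)
}

#' Audit what a masked payload discloses about the raw columns
#'
#' Compares the masked projection a site transmitted with the raw columns it
#' protects: reports the element-wise maximum absolute difference, the
#' largest column-wise Pearson correlation between payload and raw columns,
#' and whether masking was effectively disabled (payload identical to raw,
#' as happens in the degenerate g = 0 case).
#'
#' @param payload a `masked_payload` (e.g. `attr(block, "payload")`).
#' @param raw the raw column matrix the payload was derived from.
#' @return list with `max_abs_diff`, `max_abs_correlation`, `masked`
#'   (logical), `no_masking` flag.
#' @export
leakage_check <- function(payload, raw) {
  stopifnot(inherits(payload, "masked_payload"))
  raw <- as.matrix(raw)
  M <- payload$matrix
  if (!identical(dim(M), dim(raw)))
    vdra_error("vdra_dimension_error", "payload and raw dimensions differ")
  d <- max(abs(M - raw))
  cmax <- 0
  for (j in seq_len(ncol(M))) {
    if (stats::sd(M[, j]) == 0 || stats::sd(raw[, j]) == 0) next
    cmax <- max(cmax, abs(stats::cor(M[, j], raw[, j])))
  }
  list(max_abs_diff = d, max_abs_correlation = cmax,
       masked = d > 0, no_masking = d == 0)
}
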