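# Linear between-array normalization of log2 ratios.
#
# "Linear" here means a per-array affine adjustment: each event column is
# median-centered, optionally also rescaled so its median absolute
# deviation matches the grand median MAD across arrays. Both operations
# preserve within-array ranks and are exactly invertible from the report.

#' Linear (affine) per-array normalization
#'
#' @param x `expr_matrix` of log2(treatment/vehicle) ratios.
#' @param method `"median_center"` (default): subtract each column's median.
#'   `"median_center_scale"`: additionally rescale each column so its MAD
#'   equals the grand median of the column MADs.
#' @return list with `matrix` (normalized `expr_matrix`) and `report`
#'   (data.frame: one row per event with `token`, `offset`, `scale`,
#'   `method`). The input is reconstructed as `x = out/scale + offset`.
#' @export
linear_normalize <- function(x, method = c("median_center",
                                           "median_center_scale")) {
  method <- match.arg(method)
  v <- x$values
  nfin <- colSums(is.finite(v))
  if (any(nfin < 2L))
    stop("each event column needs >= 2 finite values; offending column(s): ",
         paste(colnames(v)[nfin < 2L], collapse = ", "))
  offset <- apply(v, 2L, stats::median, na.rm = TRUE)
  out <- sweep(v, 2L, offset, "-")
  scale <- rep(1, ncol(v))
  if (method == "median_center_scale") {
    mads <- apply(out, 2L, stats::mad, na.rm = TRUE)
    if (any(mads <= 0))
      stop("zero median absolute deviation in column(s): ",
           paste(colnames(v)[mads <= 0], collapse = ", "))
    target <- stats::median(mads)
    scale <- target / mads
    out <- sweep(out, 2L, scale, "*")
  }
  report <- data.frame(token = x$events$token, offset = as.numeric(offset),
                       scale = as.numeric(scale), method = method,
                       stringsAsFactors = FALSE)
  list(matrix = expr_matrix(out, x$events), report = report)
}
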