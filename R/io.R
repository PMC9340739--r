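#' Write an MRIO table to CSV
#'
#' Single-file layout: one row per region-sector pair with region and sector
#' label columns, the Z block, the final-demand block (one column per
#' destination region) and the total-output column; the primary-input row is
#' appended last with the sentinel region label "_v". Round-trips exactly.
#'
#' @param t an \code{mrio_table}.
#' @param path output file.
#' @export
write_mrio <- function(t, path) {
  lab <- rs_labels(t$regions, t$sectors)
  df <- data.frame(region = rep(t$regions, each = length(t$sectors)),
                   sector = rep(t$sectors, times = length(t$regions)),
                   t$Z, t$Fd, x = t$x, check.names = FALSE)
  colnames(df) <- c("region", "sector", paste0("Z.", lab),
                    paste0("Fd.", t$regions), "x")
  vrow <- data.frame(region = "_v", sector = "_v",
                     rbind(t$v), rbind(rep(0, length(t$regions))), x = 0,
                     check.names = FALSE)
  colnames(vrow) <- colnames(df)
  utils::write.csv(rbind(df, vrow), path, row.names = FALSE)
  invisible(path)
}

#' Read an MRIO table written by [write_mrio()]
#'
#' @param path CSV file.
#' @return an \code{mrio_table}.
#' @export
read_mrio <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vrow <- df$region == "_v"
  body <- df[!vrow, , drop = FALSE]
  regions <- unique(body$region)
  sectors <- unique(body$sector)
  zc <- grepl("^Z\\.", colnames(df))
  fc <- grepl("^Fd\\.", colnames(df))
  mrio_table(as.matrix(body[, zc]), as.matrix(body[, fc]),
             as.numeric(df[vrow, zc]), body$x, regions, sectors)
}

#' Write a gridded field to long-format CSV
#'
#' Columns lat, lon (cell indices, cell-center registered) and value.
#'
#' @param g matrix (nlat x nlon).
#' @param path output file.
#' @export
write_grid <- function(g, path) {
  df <- data.frame(lat = rep(seq_len(nrow(g)), times = ncol(g)),
                   lon = rep(seq_len(ncol(g)), each = nrow(g)),
                   value = as.vector(g))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field written by [write_grid()]
#'
#' @param path CSV file.
#' @return numeric matrix.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path)
  nlat <- max(df$lat); nlon <- max(df$lon)
  g <- matrix(0, nlat, nlon)
  g[cbind(df$lat, df$lon)] <- df$value
  g
}

#' Write a perspective emission matrix to labeled CSV
#'
#' @param Q a \code{perspective_emissions}.
#' @param path output file.
#' @export
write_perspective <- function(Q, path) {
  df <- data.frame(emitting = rownames(Q$Qmat), Q$Qmat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
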