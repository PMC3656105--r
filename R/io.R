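#' Dump the world cell states to CSV
#'
#' One row per agent: every epithelial cell (`health`, `alive`), every
#' vessel (`alive`) and every macrophage (`age`).
#'
#' @param world a `world_state`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_world_csv <- function(world, path) {
  w <- world$grid$width
  cell_xy <- function(pos) cbind(x = (pos - 1L) %% w + 1L,
                                 y = (pos - 1L) %/% w + 1L)
  ncell <- length(world$health)
  epi <- data.frame(cell_xy(seq_len(ncell)),
                    agent_type = "epithelium",
                    state = as.numeric(world$health))
  ves <- data.frame(cell_xy(world$vessel_pos),
                    agent_type = "vessel",
                    state = as.numeric(world$vessel_alive))
  mac <- if (length(world$mac_pos) > 0)
    data.frame(cell_xy(world$mac_pos), agent_type = "macrophage",
               state = as.numeric(world$mac_age))
  else NULL
  utils::write.csv(rbind(epi, ves, mac), path, row.names = FALSE)
  invisible(path)
}

#' Render a world snapshot to PNG
#'
#' Raster snapshot in the standard legend: green squares for healthy
#' epithelium, red squares for damaged epithelium, white for dead cells;
#' red discs mark living blood vessels (grey when dead) and blue discs
#' macrophages.
#'
#' @param world a `world_state`.
#' @param path output PNG path.
#' @param scale pixels per grid cell.
#' @return `path`, invisibly.
#' @export
write_world_png <- function(world, path, scale = 8) {
  w <- world$grid$width; h <- world$grid$height
  theta <- world$abm$theta_damaged
  col_of <- function(pos) (pos - 1L) %% w
  row_of <- function(pos) (pos - 1L) %/% w
  img <- array(1, dim = c(h * scale, w * scale, 3))
  paint_cell <- function(pos, rgb) {
    for (p in pos) {
      rr <- row_of(p) * scale + seq_len(scale)
      cc <- col_of(p) * scale + seq_len(scale)
      img[rr, cc, 1] <<- rgb[1]; img[rr, cc, 2] <<- rgb[2]
      img[rr, cc, 3] <<- rgb[3]
    }
  }
  paint_disc <- function(pos, rgb, radius) {
    off <- expand.grid(dy = seq_len(scale), dx = seq_len(scale))
    ctr <- (scale + 1) / 2
    off <- off[(off$dx - ctr)^2 + (off$dy - ctr)^2 <= radius^2, ]
    for (p in pos) {
      rr <- row_of(p) * scale + off$dy
      cc <- col_of(p) * scale + off$dx
      for (ch in 1:3) img[cbind(rr, cc, ch)] <<- rgb[ch]
    }
  }
  ncell <- w * h
  healthy <- which(world$alive & world$health >= theta)
  damaged <- which(world$alive & world$health < theta)
  paint_cell(healthy, c(0.20, 0.70, 0.25))
  paint_cell(damaged, c(0.85, 0.25, 0.20))
  # dead cells stay white
  ves_alive <- world$vessel_pos[world$vessel_alive]
  ves_dead <- world$vessel_pos[!world$vessel_alive]
  paint_disc(ves_alive, c(0.70, 0.05, 0.05), radius = 0.38 * scale)
  paint_disc(ves_dead, c(0.55, 0.55, 0.55), radius = 0.38 * scale)
  if (length(world$mac_pos) > 0)
    paint_disc(unique(world$mac_pos), c(0.15, 0.25, 0.85),
               radius = 0.28 * scale)
  png::writePNG(img, path)
  invisible(path)
}
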