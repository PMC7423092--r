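#' Significant voxels of a difference map
#'
#' Fo-Fc maps are effectively zero-meaned, so significance is thresholded
#' about zero: positive mode selects voxels with value `> n_sigma * sigma`,
#' negative mode `< -n_sigma * sigma`, with sigma the population standard
#' deviation over all voxels.
#'
#' @param map The Fo-Fc `ed_map`.
#' @param stats Map statistics ([map_statistics()]; computed if `NULL`).
#' @param n_sigma Sigma multiple (default 3, the Fo-Fc convention).
#' @param sign `"positive"` or `"negative"`.
#' @return Integer vector of linear voxel ids.
#' @export
significant_voxels <- function(map, stats = NULL, n_sigma = 3, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(n_sigma > 0)
  if (is.null(stats)) stats <- map_statistics(map)
  thr <- n_sigma * stats$sigma
  if (sign == "positive") which(map$grid > thr) else which(map$grid < -thr)
}

#' Partition significant voxels into connected blobs
#'
#' Maximal connected components under 26-neighbor connectivity (voxels
#' touching on faces, edges or corners belong together), wrapping across
#' periodic boundaries along axes where the map covers a full cell. Blobs
#' are sorted by decreasing |total density|.
#'
#' @param map An `ed_map` (geometry provider).
#' @param ids Linear voxel ids from [significant_voxels()].
#' @param sign Label stored on the blobs (`"positive"`/`"negative"`).
#' @param connectivity 26 (default) or 6 (face neighbors only).
#' @return An object of class `ed_blobs`: a tibble with one row per blob
#'   (`blob`, `sign`, `n_voxels`, `volume` in Angstrom^3, `total_density`,
#'   `cx`, `cy`, `cz` density-weighted centroid in Angstrom, and a `voxels`
#'   list-column of member ids).
#' @export
find_blobs <- function(map, ids, sign = "positive", connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  empty <- tibble(blob = integer(), sign = character(), n_voxels = integer(),
                  volume = numeric(), total_density = numeric(),
                  cx = numeric(), cy = numeric(), cz = numeric(),
                  voxels = list())
  class(empty) <- c("ed_blobs", class(empty))
  if (!length(ids)) return(empty)
  ids <- sort(unique(ids))
  crs <- id_to_crs(map, ids)
  key <- paste(crs[, 1], crs[, 2], crs[, 3])
  pos <- seq_along(ids)
  names(pos) <- key
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  wraps <- map_wraps(map)
  d <- dim(map$grid)
  comp <- integer(length(ids))
  ncomp <- 0L
  # BFS flood fill; unwrapped coordinates tracked for periodic-safe centroids
  unwrapped <- matrix(NA_real_, length(ids), 3)
  for (seed in seq_along(ids)) {
    if (comp[seed]) next
    ncomp <- ncomp + 1L
    comp[seed] <- ncomp
    unwrapped[seed, ] <- crs[seed, ]
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cand <- sweep(offs, 2, as.numeric(crs[cur, ]), `+`)
      cand_un <- sweep(offs, 2, unwrapped[cur, ], `+`)
      # wrap neighbor coordinates where the map covers a full cell
      for (ax in 1:3) {
        if (wraps[ax]) {
          cand[, ax] <- ((cand[, ax] - map$start[ax]) %% map$ngrid[ax]) + map$start[ax]
        }
      }
      inb <- cand[, 1] >= map$start[1] & cand[, 1] < map$start[1] + d[1] &
        cand[, 2] >= map$start[2] & cand[, 2] < map$start[2] + d[2] &
        cand[, 3] >= map$start[3] & cand[, 3] < map$start[3] + d[3]
      ck <- paste(cand[inb, 1], cand[inb, 2], cand[inb, 3])
      hit <- pos[ck]
      ok <- !is.na(hit)
      hit <- hit[ok]
      cu <- cand_un[inb, , drop = FALSE][ok, , drop = FALSE]
      is_new <- comp[hit] == 0L
      new <- hit[is_new]
      if (length(new)) {
        comp[new] <- ncomp
        unwrapped[new, ] <- cu[is_new, , drop = FALSE]
        queue <- c(queue, new)
      }
    }
  }
  vals <- map$grid[ids]
  rows <- lapply(seq_len(ncomp), function(ci) {
    sel <- comp == ci
    w <- abs(vals[sel])
    ctr_crs <- colSums(unwrapped[sel, , drop = FALSE] * w) / sum(w)
    ctr <- crs_to_xyz(map, ctr_crs)
    tibble(blob = ci, sign = sign, n_voxels = sum(sel),
           volume = sum(sel) * map$voxel_volume,
           total_density = sum(vals[sel]),
           cx = ctr[1], cy = ctr[2], cz = ctr[3],
           voxels = list(ids[sel]))
  })
  out <- bind_rows(rows) %>%
    arrange(desc(abs(.data$total_density))) %>%
    mutate(blob = row_number())
  class(out) <- c("ed_blobs", class(out))
  out
}

#' Express blob density totals in electrons
#'
#' Divides each blob's |total density| by the conversion factor (the median
#' chain density ratio from the companion 2Fo-Fc analysis) to express the
#' discrepancy in absolute electrons.
#'
#' @param blobs An `ed_blobs` tibble.
#' @param conv An `ed_conversion` (from [analyze_entry()]s result
#'   `$conversion` or [conversion_factor()]), or a positive number.
#' @return The blobs tibble with an `electrons` column.
#' @export
blob_electrons <- function(blobs, conv) {
  v <- if (inherits(conv, "ed_conversion")) conv$value else conv
  if (!isTRUE(is.finite(v) && v > 0)) {
    abort("valid conversion factor required: run the 2Fo-Fc analysis first")
  }
  blobs %>% mutate(electrons = abs(.data$total_density) / v)
}

#' Assign blobs to the nearest model atom
#'
#' Annotates each blob with the closest atom (by centroid-to-atom
#' distance) among the model atoms and, when provided, their symmetry
#' images; blobs farther than `cutoff` from every atom are left
#' unassigned.
#'
#' @param blobs An `ed_blobs` tibble.
#' @param structure The parsed model.
#' @param sym_atoms Optional tibble of symmetry image atoms from
#'   [expand_environment()].
#' @param cutoff Assignment cutoff in Angstrom (default 5).
#' @return The blobs tibble with `nearest_atom`, `nearest_resname`,
#'   `nearest_chain`, `nearest_resseq`, `distance` and `assigned` columns.
#' @export
assign_blobs <- function(blobs, structure, sym_atoms = NULL, cutoff = 5) {
  pool <- structure$atoms
  if (!is.null(sym_atoms) && nrow(sym_atoms)) {
    pool <- bind_rows(pool %>% mutate(image = FALSE),
                      sym_atoms %>% select(dplyr::any_of(names(pool))) %>%
                        mutate(image = TRUE))
  } else {
    pool <- pool %>% mutate(image = FALSE)
  }
  if (!nrow(blobs)) {
    return(blobs %>% mutate(nearest_atom = character(), nearest_resname = character(),
                            nearest_chain = character(), nearest_resseq = integer(),
                            distance = numeric(), assigned = logical()))
  }
  pm <- as.matrix(pool[, c("x", "y", "z")])
  res <- purrr::map_dfr(seq_len(nrow(blobs)), function(i) {
    d2 <- (pm[, 1] - blobs$cx[i])^2 + (pm[, 2] - blobs$cy[i])^2 + (pm[, 3] - blobs$cz[i])^2
    j <- which.min(d2)
    dist <- sqrt(d2[j])
    if (dist <= cutoff) {
      tibble(nearest_atom = pool$name[j], nearest_resname = pool$resname[j],
             nearest_chain = pool$chain[j], nearest_resseq = pool$resseq[j],
             distance = dist, assigned = TRUE)
    } else {
      tibble(nearest_atom = NA_character_, nearest_resname = NA_character_,
             nearest_chain = NA_character_, nearest_resseq = NA_integer_,
             distance = dist, assigned = FALSE)
    }
  })
  bind_cols(blobs, res)
}

#' Full difference-map workflow
#'
#' Thresholds the Fo-Fc map at `n_sigma` about zero in both signs, finds
#' connected blobs, converts their density totals to electrons with the
#' conversion factor, and assigns each blob to the nearest atom.
#'
#' @param structure The parsed model.
#' @param diff_map The Fo-Fc `ed_map`.
#' @param conv An `ed_conversion` or positive number (from the companion
#'   2Fo-Fc analysis).
#' @param n_sigma Significance threshold (default 3).
#' @param sym_atoms Optional symmetry environment for assignment.
#' @param cutoff Assignment cutoff in Angstrom.
#' @param min_voxels Drop blobs smaller than this many voxels (default 1:
#'   keep all).
#' @return An `ed_blobs` tibble covering both signs, sorted by decreasing
#'   electron content.
#' @export
analyze_difference <- function(structure, diff_map, conv, n_sigma = 3,
                               sym_atoms = NULL, cutoff = 5, min_voxels = 1L) {
  stats <- map_statistics(diff_map)
  pos <- find_blobs(diff_map, significant_voxels(diff_map, stats, n_sigma, "positive"),
                    sign = "positive")
  neg <- find_blobs(diff_map, significant_voxels(diff_map, stats, n_sigma, "negative"),
                    sign = "negative")
  out <- bind_rows(pos, neg) %>%
    filter(.data$n_voxels >= min_voxels) %>%
    blob_electrons(conv) %>%
    arrange(desc(.data$electrons)) %>%
    mutate(blob = row_number()) %>%
    assign_blobs(structure, sym_atoms = sym_atoms, cutoff = cutoff)
  class(out) <- c("ed_blobs", class(out))
  out
}

#' Plot blob electron content
#'
#' @param object An `ed_blobs` tibble with an `electrons` column.
#' @param ... Unused.
#' @return A ggplot object: electrons per blob, colored by sign, with the
#'   six-electron background band marked.
#' @method autoplot ed_blobs
#' @export
autoplot.ed_blobs <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$blob), y = .data$electrons,
                               fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 6, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(positive = "#2e7d32", negative = "#c62828")) +
    ggplot2::labs(x = "blob", y = "electrons of discrepancy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Blobs near a region of interest
#'
#' @param blobs An `ed_blobs` tibble.
#' @param structure The parsed model.
#' @param chain Chain identifier.
#' @param resseq Residue sequence number.
#' @param radius Include blobs whose centroid lies within this distance
#'   (Angstrom) of any atom of the residue.
#' @return The filtered blobs tibble.
#' @export
blobs_near_residue <- function(blobs, structure, chain, resseq, radius = 5) {
  at <- structure$atoms %>% filter(.data$chain == !!chain, .data$resseq == !!resseq)
  if (!nrow(at) || !nrow(blobs)) return(blobs[0, ])
  am <- as.matrix(at[, c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(blobs)), function(i) {
    d2 <- (am[, 1] - blobs$cx[i])^2 + (am[, 2] - blobs$cy[i])^2 + (am[, 3] - blobs$cz[i])^2
    sqrt(min(d2)) <= radius
  }, logical(1))
  blobs[keep, ]
}
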