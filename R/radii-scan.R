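# Lean evaluation path for the radius optimizer: recomputes only what a
# candidate radius changes (atom sums, chain unions, the conversion factor
# and the corrected deviation fractions), skipping the report tibbles that
# eval_cache builds. Per-entry slope vectors are held fixed during scans
# and refit only on adoption, matching the published protocol.

# per-atom f_corrected for one cache at one radii set; returns list(type, fc)
eval_fc_lean <- function(cache, radii, slopes_vec, chain_floor = 50L) {
  meta <- cache$meta
  pairs <- cache$pairs
  rad_atom <- unname(radii[meta$atom_type])
  sel <- pairs[dist <= rad_atom[atom]]
  n <- nrow(meta)
  at <- sel[, list(V = .N, total = sum(value)), by = "atom"]
  V <- integer(n); tot <- numeric(n)
  V[at$atom] <- at$V; tot[at$atom] <- at$total
  contrib <- meta$usable & !meta$partial
  selc <- sel[contrib[atom]]
  u <- unique(selc, by = c("chain", "id"))
  ch_tot <- u[, list(total = sum(value)), by = "chain"]
  chtab <- cache$chain_electrons
  idx <- match(chtab$chain, ch_tot$chain)
  r_c <- ifelse(is.na(idx), 0, ch_tot$total[idx]) / chtab$electrons
  r_c <- r_c[chtab$n_atoms >= chain_floor]
  if (!length(r_c)) abort("no qualifying chain cloud: conversion factor undefined")
  conv <- median(r_c)
  clean <- contrib & V > 0
  tpc <- meta$atom_type[clean]
  med_v <- tapply(V[clean], tpc, median)
  logb <- log(meta$b[clean])
  anchor <- median(logb)                  # structure-wide anchor
  r <- tot[clean] / (meta$z_e[clean] * meta$occ[clean])
  rn <- r * as.numeric(med_v[tpc]) / V[clean]
  f <- (rn - conv) / conv
  fc <- f - (logb - anchor) * unname(slopes_vec[tpc])
  list(type = tpc, fc = fc, conv = conv)
}

# per-atom f (uncorrected) and fitted slope table for one cache: the lean
# analogue of the slope refit performed after each radius adoption
eval_slopes_lean <- function(cache, radii, fallback, chain_floor = 50L) {
  x <- eval_f_lean(cache, radii, chain_floor = chain_floor)
  fit_bfactor_slopes(x$f, x$b, x$type, fallback = fallback)
}

# like eval_fc_lean but stops before the B-factor correction
eval_f_lean <- function(cache, radii, chain_floor = 50L) {
  meta <- cache$meta
  pairs <- cache$pairs
  rad_atom <- unname(radii[meta$atom_type])
  sel <- pairs[dist <= rad_atom[atom]]
  n <- nrow(meta)
  at <- sel[, list(V = .N, total = sum(value)), by = "atom"]
  V <- integer(n); tot <- numeric(n)
  V[at$atom] <- at$V; tot[at$atom] <- at$total
  contrib <- meta$usable & !meta$partial
  selc <- sel[contrib[atom]]
  u <- unique(selc, by = c("chain", "id"))
  ch_tot <- u[, list(total = sum(value)), by = "chain"]
  chtab <- cache$chain_electrons
  idx <- match(chtab$chain, ch_tot$chain)
  r_c <- ifelse(is.na(idx), 0, ch_tot$total[idx]) / chtab$electrons
  r_c <- r_c[chtab$n_atoms >= chain_floor]
  if (!length(r_c)) abort("no qualifying chain cloud: conversion factor undefined")
  conv <- median(r_c)
  clean <- contrib & V > 0
  tpc <- meta$atom_type[clean]
  med_v <- tapply(V[clean], tpc, median)
  r <- tot[clean] / (meta$z_e[clean] * meta$occ[clean])
  rn <- r * as.numeric(med_v[tpc]) / V[clean]
  f <- (rn - conv) / conv
  list(type = tpc, f = f, b = meta$b[clean], conv = conv)
}

# Scan support: when only one type's radius varies, everything contributed
# by the other types is frozen once per scan, and each candidate radius is
# evaluated by cumulative-sum lookups.
prep_scan <- function(cache, radii, tp, slopes_vec, chain_floor = 50L) {
  meta <- cache$meta
  pairs <- cache$pairs
  contrib <- meta$usable & !meta$partial
  is_tp <- meta$atom_type == tp
  rad_atom <- unname(radii[meta$atom_type])
  keep_fix <- contrib[pairs$atom] & !is_tp[pairs$atom] & pairs$dist <= rad_atom[pairs$atom]
  sel_fix <- pairs[keep_fix]
  ufix <- unique(sel_fix[, c("chain", "id", "value")], by = c("chain", "id"))
  sfix <- ufix[, list(total = sum(value)), by = "chain"]
  chtab <- cache$chain_electrons
  idx <- match(chtab$chain, sfix$chain)
  fix_tot <- ifelse(is.na(idx), 0, sfix$total[idx])
  at_fix <- sel_fix[, list(V = .N), by = "atom"]
  fix_clean <- at_fix$atom[at_fix$V > 0]
  fix_logb <- log(meta$b[fix_clean])      # for the structure-wide anchor
  pairs_tp <- pairs[contrib[pairs$atom] & is_tp[pairs$atom]]
  # voxels a tp atom could add to its chain union, keyed by the smallest
  # tp-atom distance; voxels already covered by the fixed part never add
  infix <- paste(pairs_tp$chain, pairs_tp$id) %in% paste(ufix$chain, ufix$id)
  add <- pairs_tp[!infix][, list(d = min(dist), value = value[1]),
                          by = c("chain", "id")]
  data.table::setorder(add, chain, d)
  add_by_chain <- split(add[, c("d", "value")], add$chain)
  add_by_chain <- lapply(add_by_chain, function(x) {
    list(d = x$d, cum = cumsum(x$value))
  })
  # per-atom sorted distances and value cumsums for the scanned type
  tp_atoms <- which(is_tp & contrib)
  data.table::setorder(pairs_tp, atom, dist)
  by_atom <- split(pairs_tp[, c("dist", "value")], pairs_tp$atom)
  atom_cum <- lapply(by_atom, function(x) list(d = x$dist, cum = cumsum(x$value)))
  list(
    chains = chtab$chain, fix_tot = fix_tot, electrons = chtab$electrons,
    qual = chtab$n_atoms >= chain_floor,
    add_by_chain = add_by_chain,
    tp_atoms = tp_atoms,
    atom_cum = atom_cum[as.character(tp_atoms)],
    z_eff = meta$z_e[tp_atoms] * meta$occ[tp_atoms],
    logb = log(meta$b[tp_atoms]),
    fix_logb = fix_logb,
    slope = unname(slopes_vec[tp])
  )
}

# corrected deviation fractions of the scanned type's atoms at radius r
eval_scan_candidate <- function(prep, r) {
  addv <- vapply(prep$chains, function(ch) {
    a <- prep$add_by_chain[[ch]]
    if (is.null(a)) return(0)
    k <- findInterval(r, a$d)
    if (k == 0) 0 else a$cum[k]
  }, numeric(1))
  r_c <- (prep$fix_tot + addv) / prep$electrons
  r_c <- r_c[prep$qual]
  if (!length(r_c)) return(numeric(0))
  conv <- median(r_c)
  nat <- length(prep$tp_atoms)
  V <- integer(nat); tot <- numeric(nat)
  for (i in seq_len(nat)) {
    a <- prep$atom_cum[[i]]
    if (is.null(a)) next
    k <- findInterval(r, a$d)
    if (k > 0) { V[i] <- k; tot[i] <- a$cum[k] }
  }
  clean <- V > 0
  if (!any(clean)) return(numeric(0))
  med_v <- median(V[clean])
  rn <- (tot[clean] / prep$z_eff[clean]) * med_v / V[clean]
  f <- (rn - conv) / conv
  lb <- prep$logb[clean]
  anchor <- median(c(prep$fix_logb, lb))
  f - (lb - anchor) * prep$slope
}

# pooled per-type medians over a sample; slopes_list: per-entry named vectors
pooled_medians <- function(caches, radii, slopes_list, chain_floor = 50L) {
  parts <- purrr::map2(caches, slopes_list, function(ca, sl) {
    eval_fc_lean(ca, radii, sl, chain_floor = chain_floor)
  })
  tp <- unlist(lapply(parts, `[[`, "type"), use.names = FALSE)
  fc <- unlist(lapply(parts, `[[`, "fc"), use.names = FALSE)
  out <- setNames(rep(NA_real_, length(atom_types())), atom_types())
  med <- tapply(fc, tp, median)
  out[names(med)] <- as.numeric(med)
  out
}
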