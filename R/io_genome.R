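# Line-oriented, tab-separated genome serialization. One gene per line:
#   pos  id  category  operator  basal  ancestry  ohnolog  dup  <payload...>
# payload (fixed order per category):
#   tf:     ligand  bind_motif  K_lig  eff_bound  eff_free
#   enzyme: reaction  k_cat  K_A  K_X
#   pump:   k_cat  K_Aext  K_X  cost
# Numbers are written with %.17g so read -> write round-trips byte-identically.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v) sprintf("%.17g", v), character(1)))
}
fmt_int <- function(x) ifelse(is.na(x), "NA", as.character(as.integer(x)))

gene_line <- function(g, pos) {
  common <- c(pos, g$id, g$category, motif_key(g$operator), fmt_num(g$basal),
              fmt_int(g$ancestry), fmt_int(g$ohnolog), as.integer(g$duplicate))
  payload <- switch(g$category,
    tf = c(g$ligand, motif_key(g$bind_motif), fmt_num(g$K_lig),
           fmt_num(g$eff_bound), fmt_num(g$eff_free)),
    enzyme = c(g$reaction, fmt_num(g$k_cat), fmt_num(g$K_A), fmt_num(g$K_X)),
    pump = c(fmt_num(g$k_cat), fmt_num(g$K_Aext), fmt_num(g$K_X), fmt_num(g$cost)))
  paste(c(common, payload), collapse = "\t")
}

#' Write / read the tab-separated genome format
#'
#' A documented line-oriented format: a `#vcg` header records the format
#' version, motif length `L`, alphabet size `S` and the genome's fresh-id
#' counter; each subsequent line is one gene (circular position, id,
#' category, operator, basal rate, ancestry and ohnolog tags, duplicate
#' flag, then the category-specific fields in fixed order). Reading a file
#' and writing it again reproduces it byte-identically.
#'
#' @param g A `vc_genome`.
#' @param path File path.
#' @return `write_genome()` returns `path` invisibly; `read_genome()` returns
#'   a `vc_genome`.
#' @export
write_genome <- function(g, path) {
  header <- sprintf("#vcg\tv1\tL=%d\tS=%d\tnext_id=%d", g$L, g$S, g$next_id)
  lines <- c(header, vapply(seq_along(g$genes),
                            function(i) gene_line(g$genes[[i]], i), character(1)))
  writeLines(lines, path)
  invisible(path)
}

parse_motif <- function(s, L, S) {
  sym <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (length(sym) != L) stop("read_genome: motif of wrong length", call. = FALSE)
  motif(sym, S)
}

num_or_na <- function(s) ifelse(s == "NA", NA_real_, as.numeric(s))
int_or_na <- function(s) ifelse(s == "NA", NA_integer_, as.integer(s))

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "#vcg"))
    stop("read_genome: missing #vcg header", call. = FALSE)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    as.integer(sub(paste0("^", key, "="), "", hit[[1]]))
  }
  L <- get_kv("L"); S <- get_kv("S"); next_id <- get_kv("next_id")
  body <- lines[-1]
  body <- body[nzchar(body)]
  genes <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- as.integer(f[[2]]); category <- f[[3]]
    op <- parse_motif(f[[4]], L, S); basal <- as.numeric(f[[5]])
    ancestry <- int_or_na(f[[6]]); ohnolog <- int_or_na(f[[7]])
    duplicate <- as.integer(f[[8]]) == 1L
    switch(category,
      tf = gene_tf(id, op, basal, ligand = f[[9]],
                   bind_motif = parse_motif(f[[10]], L, S),
                   K_lig = as.numeric(f[[11]]), eff_bound = as.numeric(f[[12]]),
                   eff_free = as.numeric(f[[13]]),
                   ancestry = ancestry, ohnolog = ohnolog, duplicate = duplicate),
      enzyme = gene_enzyme(id, op, basal, reaction = f[[9]],
                           k_cat = as.numeric(f[[10]]), K_A = as.numeric(f[[11]]),
                           K_X = as.numeric(f[[12]]),
                           ancestry = ancestry, ohnolog = ohnolog,
                           duplicate = duplicate),
      pump = gene_pump(id, op, basal, k_cat = as.numeric(f[[9]]),
                       K_Aext = as.numeric(f[[10]]), K_X = as.numeric(f[[11]]),
                       cost = as.numeric(f[[12]]),
                       ancestry = ancestry, ohnolog = ohnolog,
                       duplicate = duplicate),
      stop("read_genome: unknown category ", category, call. = FALSE))
  })
  genome(genes, L = L, S = S, next_id = next_id)
}
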