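#' Fetch an organism's reaction set from the KEGG REST interface
#'
#' Downloads the organism's gene-to-reaction links and the corresponding
#' reaction entries, writes them to \code{cache_dir/<org_code>/reactions.txt}
#' in the same flat format \code{\link{parse_reaction_flatfile}} reads, and
#' returns the parsed records. Once the cache is warm, repeated calls are
#' fully offline and byte-identical.
#'
#' @param org_code KEGG organism code (e.g. \code{"sgo"}).
#' @param cache_dir directory holding per-organism caches.
#' @param base_url root of the KEGG REST service.
#' @param refresh if \code{TRUE}, ignore an existing cache and re-download.
#' @return list of \code{reaction_record}.
#' @export
fetch_org_metabolic_data <- function(org_code, cache_dir,
                                     base_url = "https://rest.kegg.jp",
                                     refresh = FALSE) {
  org_code <- trimws(as.character(org_code)[1])
  if (!nzchar(org_code)) {
    stop("unknown organism code: empty string", call. = FALSE)
  }
  cache_file <- file.path(cache_dir, org_code, "reactions.txt")
  if (!refresh && file.exists(cache_file)) {
    return(parse_reaction_flatfile(cache_file))
  }
  lines <- kegg_download_reactions(org_code, base_url)
  dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, cache_file)
  parse_reaction_flatfile(cache_file)
}

kegg_get <- function(url) {
  txt <- tryCatch(readLines(url, warn = FALSE),
                  error = function(e) {
                    stop("KEGG REST request failed (network unavailable and no cache?): ",
                         url, " -- ", conditionMessage(e), call. = FALSE)
                  })
  txt
}

kegg_download_reactions <- function(org_code, base_url) {
  link <- kegg_get(sprintf("%s/link/reaction/%s", base_url, org_code))
  link <- link[nzchar(link)]
  if (length(link) == 0L) {
    stop("unknown organism code or no reactions linked: ", org_code,
         call. = FALSE)
  }
  rids <- unique(sub("^rn:", "", vapply(strsplit(link, "\t"), `[`, "", 2)))
  rids <- sort(rids[grepl("^R\\d{5}$", rids)])
  # KEGG serves up to 10 entries per GET
  chunks <- split(rids, ceiling(seq_along(rids) / 10))
  unlist(lapply(chunks, function(ch) {
    kegg_get(sprintf("%s/get/%s", base_url,
                     paste(paste0("rn:", ch), collapse = "+")))
  }), use.names = FALSE)
}
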