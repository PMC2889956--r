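# Hand-entered study fixture: the 31 iguanian taxa (9 agamids, 12
# chamaeleonids, 10 iguanids) with published mtDNA/control-region lengths,
# their mitogenome-arrangement character states, and the mitogenomic
# phylogeny entered from the relationships stated for these families and
# subfamilies. Control-region lengths are absent for the three genomes
# whose repeat-rich CRs could not be sequenced through (plus one further
# unresolved iguanid CR).

fixture_table <- function() {
  tibble::tribble(
    ~taxon, ~family, ~accession, ~genome_length, ~cr_length,
    "Uromastyx_benti", "Agamidae", "AB114447", 16380L, 990L,
    "Leiolepis_guttata", "Agamidae", "AB476400", 16552L, 1167L,
    "Pogona_vitticeps", "Agamidae", "AB166795", 16751L, 798L,
    "Chlamydosaurus_kingii", "Agamidae", "EF090422", 16761L, 812L,
    "Hydrosaurus_amboinensis", "Agamidae", "AB475096", 16129L, 823L,
    "Calotes_versicolor", "Agamidae", "AB183287", 16670L, 1504L,
    "Acanthosaura_armata", "Agamidae", "AB266452", 16544L, 1463L,
    "Pseudotrapelus_sinaitus", "Agamidae", "AB262447", 16560L, 1456L,
    "Xenagama_taylori", "Agamidae", "DQ008215", 16220L, 1174L,
    "Calumma_parsonii", "Chamaeleonidae", "AB474915", 17497L, 2182L,
    "Trioceros_melleri", "Chamaeleonidae", "AB474916", 16832L, 1521L,
    "Chamaeleo_calcaricarens", "Chamaeleonidae", "EF222195", 17451L, 2189L,
    "Chamaeleo_chamaeleon", "Chamaeleonidae", "EF222201", 17415L, 2155L,
    "Chamaeleo_calyptratus", "Chamaeleonidae", "EF222192", 17433L, 2178L,
    "Chamaeleo_zeylanicus", "Chamaeleonidae", "EF222191", 18923L, 3665L,
    "Chamaeleo_monachus", "Chamaeleonidae", "EF222190", 18900L, 3672L,
    "Chamaeleo_dilepis", "Chamaeleonidae", "EF222189", 17875L, 2618L,
    "Furcifer_oustaleti", "Chamaeleonidae", "AB185326", 18021L, 2785L,
    "Kinyongia_fischeri", "Chamaeleonidae", "AB474917", 17400L, NA,
    "Rieppeleon_kerstenii", "Chamaeleonidae", "AB474918", 17982L, NA,
    "Brookesia_decaryi", "Chamaeleonidae", "AB474914", 17324L, 2094L,
    "Anolis_cybotes", "Iguanidae", "AB218960", 17853L, NA,
    "Basiliscus_vittatus", "Iguanidae", "AB218883", 16948L, 1562L,
    "Gambelia_wislizenii", "Iguanidae", "AB218884", 17563L, 2181L,
    "Iguana_iguana", "Iguanidae", "AJ278511", 16633L, 1191L,
    "Oplurus_grandidieri", "Iguanidae", "AB218720", 17122L, 1758L,
    "Chalarodon_madagascariensis", "Iguanidae", "AB266748", 16851L, 1493L,
    "Polychrus_marmoratus", "Iguanidae", "AB266749", 17743L, 2371L,
    "Leiocephalus_personatus", "Iguanidae", "AB266739", 16681L, 1316L,
    "Plica_plica", "Iguanidae", "AB218961", 17643L, NA,
    "Sceloporus_occidentalis", "Iguanidae", "AB079242", 17072L, 1689L
  )
}

fixture_characters <- function() {
  tab <- fixture_table()
  acrodont <- tab$family %in% c("Agamidae", "Chamaeleonidae")
  inverted_p <- c("Calotes_versicolor", "Acanthosaura_armata")
  translocated_p <- c("Pseudotrapelus_sinaitus", "Xenagama_taylori",
                      tab$taxon[tab$family == "Chamaeleonidae"])
  duplicate_cr <- c("Pogona_vitticeps", "Chlamydosaurus_kingii")
  ol_absent <- c("Uromastyx_benti", "Hydrosaurus_amboinensis",
                 "Pogona_vitticeps", "Chlamydosaurus_kingii")
  tibble::tibble(
    taxon = tab$taxon,
    C1 = ifelse(acrodont, "QIM", "IQM"),
    C2 = dplyr::case_when(
      tab$taxon %in% inverted_p ~ "inverted",
      tab$taxon %in% translocated_p ~ "translocated_3prime_CR",
      TRUE ~ "typical"
    ),
    C3 = ifelse(tab$taxon %in% duplicate_cr, "duplicate_ND5_ND6", "single"),
    C4 = ifelse(tab$taxon %in% ol_absent, "absent", "present"),
    C5 = ifelse(tab$taxon == "Acanthosaura_armata", "CGG", "TGG")
  )
}

fixture_newick <- function() {
  paste0(
    "((",
    "(Oplurus_grandidieri,Chalarodon_madagascariensis)Oplurinae,",
    "(Anolis_cybotes,Basiliscus_vittatus,Gambelia_wislizenii,",
    "Iguana_iguana,Polychrus_marmoratus,Leiocephalus_personatus,",
    "Plica_plica,Sceloporus_occidentalis)",
    ")Iguanidae,(",
    "(Uromastyx_benti,(Leiolepis_guttata,((Pogona_vitticeps,",
    "Chlamydosaurus_kingii)Amphibolurinae,(Hydrosaurus_amboinensis,",
    "((Pseudotrapelus_sinaitus,Xenagama_taylori)Agaminae,",
    "(Calotes_versicolor,Acanthosaura_armata)Draconinae)))))Agamidae,",
    "(Brookesia_decaryi,(Rieppeleon_kerstenii,(",
    "(Chamaeleo_calcaricarens,Chamaeleo_chamaeleon,Chamaeleo_calyptratus,",
    "Chamaeleo_zeylanicus,Chamaeleo_monachus,Chamaeleo_dilepis)Chamaeleo,",
    "(Kinyongia_fischeri,(Trioceros_melleri,(Calumma_parsonii,",
    "Furcifer_oustaleti))))))Chamaeleonidae",
    ")Acrodonta)Iguania;"
  )
}

# Nominal (typical vertebrate) mt gene lengths used to lay fixture and
# simulated features onto coordinates; only the order and strands carry
# information, the published per-gene coordinates are not reproduced.
nominal_lengths <- function() {
  c("F" = 70, "12S" = 950, "V" = 70, "16S" = 1600, "L(UUR)" = 75,
    "ND1" = 960, "I" = 70, "Q" = 70, "M" = 70, "ND2" = 1040, "W" = 70,
    "A" = 70, "N" = 70, "OL" = 35, "C" = 65, "Y" = 70, "COI" = 1550,
    "S(UCN)" = 70, "D" = 70, "COII" = 690, "K" = 70, "ATP8" = 165,
    "ATP6" = 680, "COIII" = 785, "G" = 70, "ND3" = 350, "R" = 70,
    "ND4L" = 300, "ND4" = 1380, "H" = 70, "S(AGY)" = 65, "L(CUN)" = 70,
    "ND5" = 1820, "ND6" = 520, "E" = 70, "CYTB" = 1140, "T" = 70,
    "P" = 70, "CR" = 1000)
}

# Feature table (nominal coordinates) for a gene order.
order_to_features <- function(order, cr_length = NA) {
  lens <- nominal_lengths()
  len <- unname(lens[base_symbol(order$name)])
  if (!is.na(cr_length)) {
    len[base_symbol(order$name) == "CR"] <- cr_length
  }
  end <- cumsum(len)
  tibble::tibble(
    name = order$name,
    start = as.integer(end - len + 1L),
    end = as.integer(end),
    strand = ifelse(order$orientation == "+", "H", "L"),
    feature_class = order$feature_class
  )
}

#' Build a gene order realising a set of arrangement-character states
#'
#' Starts from the typical vertebrate arrangement and applies the
#' rearrangements implied by the supplied states: the IQM-to-QIM tRNA
#' cluster swap, tRNA-Pro strand inversion or translocation to the 3'
#' side of the control region, insertion of a duplicate control region
#' between ND5 and ND6 (`CR-1`/`CR-2` suffixed in genome order), and loss
#' of the light-strand replication origin. Anticodon state (`C5`) has no
#' gene-order footprint.
#'
#' @param states One-row tibble (or named list) with any of `C1`..`C4`.
#' @return A `gene_order` anchored at `F`.
#' @export
apply_rearrangements <- function(states) {
  ord <- canonical_vertebrate_order()
  nm <- ord$name
  ori <- ord$orientation
  get <- function(ch, default) {
    v <- states[[ch]]
    if (is.null(v) || is.na(v)) default else v
  }
  if (get("C1", "IQM") == "QIM") {
    i <- match("I", nm); q <- match("Q", nm)
    nm[c(i, q)] <- nm[c(q, i)]
    ori[c(i, q)] <- ori[c(q, i)]
  }
  c2 <- get("C2", "typical")
  if (c2 == "inverted") {
    ori[match("P", nm)] <- "+"
  } else if (c2 == "translocated_3prime_CR") {
    p <- match("P", nm)
    p_ori <- ori[p]
    nm <- c(nm[-p], "P")
    ori <- c(ori[-p], p_ori)
  }
  if (get("C3", "single") == "duplicate_ND5_ND6") {
    nd6 <- match("ND6", nm)
    nm[nm == "CR"] <- "CR-2"
    nm <- append(nm, "CR-1", after = nd6 - 1L)
    ori <- append(ori, "+", after = nd6 - 1L)
  }
  if (get("C4", "present") == "absent") {
    keep <- nm != "OL"
    nm <- nm[keep]; ori <- ori[keep]
  }
  new_gene_order(nm, ori, anchor = "F")
}

#' The packaged 31-taxon iguanian study fixture
#'
#' Hand-entered comparative data for the 31 iguanian mitogenomes: per-taxon
#' metadata (family, accession, genome and control-region lengths, the
#' latter absent for the four taxa whose CRs are unresolved), the
#' arrangement-character matrix, and the mitogenomic tree topology for
#' these taxa (subfamily-level relationships; within-group polytomies
#' where relationships are not relied upon). Feature tables realise each
#' taxon's character states on nominal vertebrate gene lengths — gene
#' order and strand are faithful, per-gene coordinates are nominal.
#'
#' @return List with elements `records` (31-row mitogenome-record
#'   tibble), `characters` (taxon x `C1`..`C5` tibble), `tree`
#'   (`ape::phylo`, rooted, internal nodes labelled with clade names) and
#'   `newick` (the topology string).
#' @examples
#' fx <- study_fixture()
#' nrow(fx$records)
#' mean_cr_length(fx$records)
#' @export
study_fixture <- function() {
  tab <- fixture_table()
  chars <- fixture_characters()
  records <- purrr::map(seq_len(nrow(tab)), function(i) {
    st <- chars[i, ]
    ord <- apply_rearrangements(st)
    new_mitogenome_record(
      taxon = tab$taxon[i], family = tab$family[i],
      features = order_to_features(ord, cr_length = tab$cr_length[i]),
      genome_length = tab$genome_length[i],
      cr_length = tab$cr_length[i],
      accession = tab$accession[i]
    )
  }) |> dplyr::bind_rows()
  list(
    records = records,
    characters = chars,
    tree = ape::read.tree(text = fixture_newick()),
    newick = fixture_newick()
  )
}
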