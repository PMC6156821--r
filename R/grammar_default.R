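# The shipped grammar: 154 rule templates (95 syntax, 59 surface) across 10
# categories. Event-side syntax templates encode the recurring syntactic
# variations (declarative, passive, three nominalizations, subject/object
# relative clauses, subject/object appositions, paraphrastic causatives)
# and their site/light-verb refinements; combinations (e.g. a passive
# inside a relative clause) fall out of path composition. Surface templates
# cover entity recognition, state attachment and parse-free fallbacks.

CAUSATIVE_LEX <- paste(
  c("cause", "causes", "caused", "causing", "induce", "induces", "induced",
    "inducing", "trigger", "triggers", "triggered", "drive", "drives",
    "drove", "driven", "promote", "promotes", "promoted", "promoting",
    "mediate", "mediates", "mediated"), collapse = "|")
UNDERGO_LEX <- "undergo|undergoes|underwent|undergone|undergoing"
FORM_LEX <- "form|forms|formed|forming"

.role <- function(path, required = TRUE, kind = "entity", types = NULL) {
  list(path = path, required = required, kind = kind, types = types)
}
.syn <- function(name, category, trigger_pos, roles, forbid = character(0)) {
  rule_template(name, category, "syntax", trigger_pos = trigger_pos,
                roles = roles, forbid = forbid)
}
.sur <- function(name, category, pattern) {
  rule_template(name, category, "surface", pattern = pattern)
}

SITE_T <- "site"
CC_T <- "cellular_component"

default_grammar_build <- function() {
  g <- list()
  add <- function(x) g[[length(g) + 1L]] <<- x

  # --- entities: 15 surface ------------------------------------------------
  add(.sur("ent-kb-protein", "entity", "K:gene_or_gene_product"))
  add(.sur("ent-kb-family", "entity", "K:family"))
  add(.sur("ent-kb-chemical", "entity", "K:simple_chemical"))
  add(.sur("ent-kb-cellular-component", "entity", "K:cellular_component"))
  add(.sur("ent-kb-site", "entity", "K:site"))
  add(.sur("ent-site-residue-long", "entity",
           "R:^(Ser|Thr|Tyr|Lys|Arg|His|Cys|Asp|Glu)[0-9]+$:site"))
  add(.sur("ent-site-residue-short", "entity", "R:^[STYKRH][0-9]+$:site"))
  add(.sur("ent-site-residue-worded", "entity",
           "W:residue? R:^(Ser|Thr|Tyr|Lys|Arg|His|Cys|Asp|Glu)$:res R:^[0-9]+$:pos"))
  add(.sur("ent-site-paren", "entity",
           "R:^(Ser|Thr|Tyr|Lys|Arg|His)$:res W:( R:^[0-9]+$:pos W:)"))
  add(.sur("ent-protein-p-morphology", "entity", "R:^p[0-9]{2,3}$:name"))
  add(.sur("ent-cc-head-noun", "entity",
           paste0("R:^(nucleus|cytoplasm|cytosol|nucleolus|membrane|",
                  "mitochondrion|mitochondria|endosome|lysosome|ribosome|",
                  "proteasome)$:name")))
  add(.sur("ent-cc-compound", "entity",
           "W:plasma|cell|outer|inner R:^membrane$:name"))
  add(.sur("ent-family-suffix", "entity", "E:base W:family"))
  add(.sur("ent-protein-greek", "entity",
           "E:base W:- R:^(alpha|beta|gamma|delta|epsilon)$:suffix"))
  add(.sur("ent-nucleotide-morphology", "entity", "R:^[cd]?[AGCU][MDT]P$:name"))

  # --- generic entities: 2 surface ----------------------------------------
  add(.sur("gen-singular", "generic_entity",
           paste0("W:this|that|the R:^(protein|kinase|phosphatase|enzyme|",
                  "receptor|ligase|factor|molecule|substrate)$:head")))
  add(.sur("gen-plural", "generic_entity",
           paste0("W:these|those|both R:^(proteins|kinases|phosphatases|",
                  "enzymes|receptors|factors|molecules)$:head")))

  # --- modifications: 6 surface -------------------------------------------
  ptm_part <- paste0("^(phosphorylated|ubiquitinated|hydroxylated|sumoylated|",
                     "glycosylated|acetylated|farnesylated|ribosylated|",
                     "methylated)$")
  add(.sur("mod-ptm-prefix-dash", "modification",
           paste0("R:^(phospho|ubiquitin|acetyl|methyl|sumo|glyco|hydroxy|",
                  "farnesyl|ribosyl)$:prefix W:- E:target")))
  add(.sur("mod-ptm-participle", "modification",
           paste0("R:", ptm_part, ":state E:target")))
  add(.sur("mod-ptm-participle-site", "modification",
           paste0("E:target R:", ptm_part, ":state W:at|on E:site:site")))
  add(.sur("mod-wildtype-premod", "modification", "W:wild W:-? W:type E:target"))
  add(.sur("mod-wildtype-suffix", "modification", "E:target W:- R:^WT$:state"))
  add(.sur("mod-ptm-poly-prefix", "modification",
           paste0("R:^(mono|di|poly)$:mult W:- R:", ptm_part, ":state E:target")))

  # --- mutants: 9 surface --------------------------------------------------
  code <- "R:^[A-Z][0-9]+[A-Z]$:code"
  add(.sur("mut-dash-code", "mutant", paste("E:target W:-", code)))
  add(.sur("mut-code-premod", "mutant", paste(code, "E:target")))
  add(.sur("mut-code-of", "mutant", paste(code, "W:mutant W:of E:target")))
  add(.sur("mut-code-anaphoric", "mutant", paste("W:the|this", code, "W:mutant")))
  add(.sur("mut-premod", "mutant", "W:mutant E:target"))
  add(.sur("mut-postmod", "mutant", "E:target W:mutant"))
  add(.sur("mut-paren", "mutant", paste("E:target W:(", code, "W:)")))
  add(.sur("mut-substitution", "mutant", paste(code, "W:substitution|mutation")))
  add(.sur("mut-delta", "mutant", "R:^(Δ|delta)$:del E:target"))

  # --- simple events: 15 syntax -------------------------------------------
  sc <- "simple_event"
  add(.syn("se-declarative", sc, "verb", list(
    theme = .role(">obj|dobj"), cause = .role(">nsubj", FALSE, "either"))))
  add(.syn("se-passive", sc, "verb", list(
    theme = .role(">nsubj:pass"),
    cause = .role(">obl:by|nmod:by", FALSE, "either"))))
  add(.syn("se-prep-nominal", sc, "noun", list(
    theme = .role(">nmod:of"), cause = .role(">nmod:by", FALSE, "either"))))
  add(.syn("se-obj-nominal-by", sc, "noun", list(
    theme = .role(">compound"), cause = .role(">nmod:by", TRUE, "either"))))
  add(.syn("se-subj-nominal", sc, "noun", list(
    cause = .role(">compound", TRUE, "either"), theme = .role(">nmod:of"))))
  add(.syn("se-subj-relative", sc, "verb", list(
    cause = .role("<xcomp? <acl:relcl", TRUE, "either"),
    theme = .role(">obj|dobj"))))
  add(.syn("se-obj-relative", sc, "verb", list(
    theme = .role("<acl:relcl"),
    cause = .role(">obl:by|nmod:by", FALSE, "either")), forbid = ">nsubj"))
  add(.syn("se-subj-apposition", sc, "verb", list(
    theme = .role(">obj|dobj"),
    cause = .role(">nsubj >appos", TRUE, "either"))))
  add(.syn("se-obj-apposition", sc, "verb", list(
    theme = .role(">obj|dobj >appos"),
    cause = .role(">nsubj", FALSE, "either"))))
  add(.syn("se-paraphrastic-causative", sc, "noun", list(
    theme = .role(">nmod:of"),
    cause = .role(paste0("<obj~", CAUSATIVE_LEX, " >nsubj"), TRUE, "either"))))
  add(.syn("se-obj-nominal-bare", sc, "noun", list(
    theme = .role(">compound")), forbid = ">nmod:of"))
  add(.syn("se-declarative-site", sc, "verb", list(
    theme = .role(">obj|dobj"),
    site = .role(">obl:at|nmod:at|obl:on|nmod:on", TRUE, "entity", SITE_T),
    cause = .role(">nsubj", FALSE, "either"))))
  add(.syn("se-nominal-site", sc, "noun", list(
    theme = .role(">nmod:of"),
    site = .role(">nmod:at|nmod:on", TRUE, "entity", SITE_T))))
  add(.syn("se-passive-site", sc, "verb", list(
    theme = .role(">nsubj:pass"),
    site = .role(">obl:at|nmod:at|obl:on|nmod:on", TRUE, "entity", SITE_T),
    cause = .role(">obl:by", FALSE, "either"))))
  add(.syn("se-light-verb-undergo", sc, "noun", list(
    theme = .role(paste0("<obj~", UNDERGO_LEX, " >nsubj")))))

  # --- simple events: 11 surface (parse-free fallbacks) --------------------
  add(.sur("se-sur-nominal-of", sc, "T W:of E:theme"))
  add(.sur("se-sur-compound", sc, "E:theme T"))
  add(.sur("se-sur-nominal-of-by", sc, "T W:of E:theme W:by E:cause"))
  add(.sur("se-sur-compound-by", sc, "E:theme T W:by E:cause"))
  add(.sur("se-sur-mediated", sc, "E:cause W:- W:mediated T"))
  add(.sur("se-sur-nominal-of-at", sc, "T W:of E:theme W:at E:site:site"))
  add(.sur("se-sur-dependent", sc, "E:cause W:- W:dependent T"))
  add(.sur("se-sur-compound-at", sc, "E:theme T W:at E:site:site"))
  add(.sur("se-sur-copular-passive", sc, "E:theme W:is|was|are|were T"))
  add(.sur("se-sur-nominal-of-on", sc, "T W:of E:theme W:on E:site:site"))
  add(.sur("se-sur-declarative", sc, "E:cause T E:theme"))

  # --- binding: 30 syntax --------------------------------------------------
  bc <- "binding"
  b2 <- function(p1, p2) list(theme1 = .role(p1), theme2 = .role(p2))
  add(.syn("bind-declarative-obj", bc, "verb", b2(">nsubj", ">obj|dobj")))
  add(.syn("bind-declarative-to", bc, "verb", b2(">nsubj", ">obl:to|nmod:to")))
  add(.syn("bind-declarative-with", bc, "verb", b2(">nsubj", ">obl:with|nmod:with")))
  add(.syn("bind-passive-by", bc, "verb", b2(">nsubj:pass", ">obl:by|nmod:by")))
  add(.syn("bind-passive-to", bc, "verb", b2(">nsubj:pass", ">obl:to|nmod:to")))
  add(.syn("bind-passive-with", bc, "verb", b2(">nsubj:pass", ">obl:with|nmod:with")))
  add(.syn("bind-subj-relative-obj", bc, "verb", b2("<xcomp? <acl:relcl", ">obj|dobj")))
  add(.syn("bind-subj-relative-to", bc, "verb", b2("<xcomp? <acl:relcl", ">obl:to|nmod:to")))
  add(.syn("bind-subj-relative-with", bc, "verb", b2("<xcomp? <acl:relcl", ">obl:with|nmod:with")))
  add(.syn("bind-obj-relative-by", bc, "verb", b2("<acl:relcl", ">obl:by|nmod:by"),
           forbid = ">nsubj"))
  add(.syn("bind-obj-relative-to", bc, "verb", b2("<acl:relcl", ">obl:to|nmod:to"),
           forbid = ">nsubj"))
  add(.syn("bind-obj-relative-with", bc, "verb", b2("<acl:relcl", ">obl:with|nmod:with"),
           forbid = ">nsubj"))
  add(.syn("bind-subj-appos-obj", bc, "verb", b2(">nsubj >appos", ">obj|dobj")))
  add(.syn("bind-subj-appos-to", bc, "verb", b2(">nsubj >appos", ">obl:to|nmod:to")))
  add(.syn("bind-subj-appos-with", bc, "verb", b2(">nsubj >appos", ">obl:with|nmod:with")))
  add(.syn("bind-obj-appos-obj", bc, "verb", b2(">nsubj", ">obj|dobj >appos")))
  add(.syn("bind-obj-appos-to", bc, "verb", b2(">nsubj", ">obl:to|nmod:to >appos")))
  add(.syn("bind-obj-appos-with", bc, "verb", b2(">nsubj", ">obl:with|nmod:with >appos")))
  add(.syn("bind-nominal-of-with", bc, "noun", b2(">nmod:of", ">nmod:with")))
  add(.syn("bind-nominal-of-to", bc, "noun", b2(">nmod:of", ">nmod:to")))
  add(.syn("bind-nominal-between", bc, "noun", b2(">nmod:between", ">nmod:between >conj")))
  add(.syn("bind-nominal-compound-pair", bc, "noun", b2(">compound", ">compound")))
  add(.syn("bind-nominal-of-and", bc, "noun", b2(">nmod:of", ">nmod:of >conj")))
  add(.syn("bind-nominal-poss", bc, "noun", b2(">nmod:poss", ">nmod:with|nmod:to")))
  add(.syn("bind-complex-form-with", bc, "noun",
           b2(paste0("<obj~", FORM_LEX, " >nsubj"), ">nmod:with|obl:with")))
  add(.syn("bind-complex-form-between", bc, "noun",
           b2(paste0("<obj~", FORM_LEX, " >nsubj"), ">nmod:between")))
  add(.syn("bind-paraphrastic-of-to", bc, "noun", c(
    b2(">nmod:of", ">nmod:to"),
    list(cause = .role(paste0("<obj~", CAUSATIVE_LEX, " >nsubj"), FALSE, "either")))))
  add(.syn("bind-paraphrastic-of-with", bc, "noun", c(
    b2(">nmod:of", ">nmod:with"),
    list(cause = .role(paste0("<obj~", CAUSATIVE_LEX, " >nsubj"), FALSE, "either")))))
  add(.syn("bind-reciprocal-subj-conj", bc, "verb", b2(">nsubj", ">nsubj >conj")))
  add(.syn("bind-copular-complex-with", bc, "noun", b2(">nsubj", ">nmod:with")))

  # --- binding: 7 surface --------------------------------------------------
  add(.sur("bind-sur-to", bc, "E:theme1 T W:to E:theme2"))
  add(.sur("bind-sur-with", bc, "E:theme1 T W:with E:theme2"))
  add(.sur("bind-sur-between", bc, "T W:between E:theme1 W:and E:theme2"))
  add(.sur("bind-sur-of-to", bc, "T W:of E:theme1 W:to E:theme2"))
  add(.sur("bind-sur-of-with", bc, "T W:of E:theme1 W:with E:theme2"))
  add(.sur("bind-sur-slash-pair", bc, "E:theme1 W:/ E:theme2 T"))
  add(.sur("bind-sur-dash-pair", bc, "E:theme1 W:- E:theme2 T"))

  # --- hydrolysis: 8 syntax, 2 surface ------------------------------------
  hc <- "hydrolysis"
  add(.syn("hyd-declarative", hc, "verb", list(
    theme = .role(">obj|dobj"), cause = .role(">nsubj", FALSE, "either"))))
  add(.syn("hyd-passive", hc, "verb", list(
    theme = .role(">nsubj:pass"),
    cause = .role(">obl:by|nmod:by", FALSE, "either"))))
  add(.syn("hyd-prep-nominal", hc, "noun", list(
    theme = .role(">nmod:of"), cause = .role(">nmod:by", FALSE, "either"))))
  add(.syn("hyd-obj-nominal-bare", hc, "noun", list(
    theme = .role(">compound")), forbid = ">nmod:of"))
  add(.syn("hyd-subj-relative", hc, "verb", list(
    cause = .role("<xcomp? <acl:relcl", TRUE, "either"),
    theme = .role(">obj|dobj"))))
  add(.syn("hyd-obj-relative", hc, "verb", list(
    theme = .role("<acl:relcl"),
    cause = .role(">obl:by|nmod:by", FALSE, "either")), forbid = ">nsubj"))
  add(.syn("hyd-paraphrastic", hc, "noun", list(
    theme = .role(">nmod:of"),
    cause = .role(paste0("<obj~", CAUSATIVE_LEX, " >nsubj"), TRUE, "either"))))
  add(.syn("hyd-apposition", hc, "verb", list(
    theme = .role(">obj|dobj >appos"),
    cause = .role(">nsubj >appos?", FALSE, "either"))))
  add(.sur("hyd-sur-nominal-of", hc, "T W:of E:theme"))
  add(.sur("hyd-sur-compound", hc, "E:theme T"))

  # --- translocation: 12 syntax -------------------------------------------
  tc <- "translocation"
  dst <- function(p, req = TRUE) .role(p, req, "entity", CC_T)
  add(.syn("loc-declarative-to", tc, "verb", list(
    theme = .role(">nsubj"), destination = dst(">obl:to|obl:into|nmod:to|nmod:into"),
    source = dst(">obl:from|nmod:from", FALSE))))
  add(.syn("loc-declarative-from", tc, "verb", list(
    theme = .role(">nsubj"), source = dst(">obl:from|nmod:from"),
    destination = dst(">obl:to|obl:into", FALSE))))
  add(.syn("loc-transitive", tc, "verb", list(
    cause = .role(">nsubj", FALSE, "either"), theme = .role(">obj|dobj"),
    destination = dst(">obl:to|obl:into", FALSE),
    source = dst(">obl:from", FALSE))))
  add(.syn("loc-passive", tc, "verb", list(
    theme = .role(">nsubj:pass"), source = dst(">obl:from", FALSE),
    destination = dst(">obl:to|obl:into", FALSE),
    cause = .role(">obl:by", FALSE, "either"))))
  add(.syn("loc-nominal-of-to", tc, "noun", list(
    theme = .role(">nmod:of"), destination = dst(">nmod:to|nmod:into"))))
  add(.syn("loc-nominal-of-from", tc, "noun", list(
    theme = .role(">nmod:of"), source = dst(">nmod:from"),
    destination = dst(">nmod:to|nmod:into", FALSE))))
  add(.syn("loc-nominal-compound", tc, "noun", list(
    theme = .role(">compound"), destination = dst(">nmod:to|nmod:into"))))
  add(.syn("loc-subj-relative", tc, "verb", list(
    theme = .role("<xcomp? <acl:relcl"),
    destination = dst(">obl:to|obl:into"), source = dst(">obl:from", FALSE))))
  add(.syn("loc-obj-relative", tc, "verb", list(
    theme = .role("<acl:relcl"), destination = dst(">obl:to|obl:into", FALSE),
    source = dst(">obl:from", FALSE),
    cause = .role(">obl:by", FALSE, "either")), forbid = ">nsubj"))
  add(.syn("loc-paraphrastic", tc, "noun", list(
    theme = .role(">nmod:of"),
    cause = .role(paste0("<obj~", CAUSATIVE_LEX, " >nsubj"), TRUE, "either"),
    destination = dst(">nmod:to|nmod:into", FALSE))))
  add(.syn("loc-declarative-in", tc, "verb", list(
    theme = .role(">nsubj"), destination = dst(">obl:in|nmod:in"))))
  add(.syn("loc-nominal-in", tc, "noun", list(
    theme = .role(">nmod:of"), destination = dst(">nmod:in"))))

  # --- positive regulation / activation: 16 syntax, 4 surface --------------
  pc <- "positive_regulation_activation"
  ctrl <- function(p, req = TRUE) .role(p, req, "either")
  add(.syn("pos-declarative", pc, "verb", list(
    controller = ctrl(">nsubj >compound|nmod:of?"),
    controlled = ctrl(">obj|dobj"))))
  add(.syn("pos-declarative-prep", pc, "verb", list(
    controller = ctrl(">nsubj >compound|nmod:of?"),
    controlled = ctrl(">obl:in|obl:to|nmod:in|nmod:to"))))
  add(.syn("pos-passive", pc, "verb", list(
    controlled = ctrl(">nsubj:pass"), controller = ctrl(">obl:by|nmod:by"))))
  add(.syn("pos-nominal-of-by", pc, "noun", list(
    controlled = ctrl(">nmod:of"), controller = ctrl(">nmod:by"))))
  add(.syn("pos-nominal-compound-of", pc, "noun", list(
    controller = ctrl(">compound"), controlled = ctrl(">nmod:of"))))
  add(.syn("pos-nominal-obj-compound", pc, "noun", list(
    controlled = ctrl(">compound"), controller = ctrl(">nmod:by"))))
  add(.syn("pos-subj-relative", pc, "verb", list(
    controller = ctrl("<xcomp? <acl:relcl"), controlled = ctrl(">obj|dobj"))))
  add(.syn("pos-obj-relative", pc, "verb", list(
    controlled = ctrl("<acl:relcl"), controller = ctrl(">obl:by|nmod:by")),
    forbid = ">nsubj"))
  add(.syn("pos-subj-appos", pc, "verb", list(
    controller = ctrl(">nsubj >appos"), controlled = ctrl(">obj|dobj"))))
  add(.syn("pos-obj-appos", pc, "verb", list(
    controller = ctrl(">nsubj"), controlled = ctrl(">obj|dobj >appos"))))
  add(.syn("pos-passive-obl-in", pc, "verb", list(
    controlled = ctrl(">nsubj:pass >compound?"),
    controller = ctrl(">obl:in|nmod:in >compound?"))))
  add(.syn("pos-nominal-poss", pc, "noun", list(
    controller = ctrl(">nmod:poss"), controlled = ctrl(">nmod:of"))))
  add(.syn("pos-mediated-amod", pc, "any", list(
    controller = ctrl(">compound|obl:npmod"), controlled = ctrl("<amod"))))
  add(.syn("pos-declarative-ccomp", pc, "verb", list(
    controller = ctrl(">nsubj"),
    controlled = .role(">ccomp", TRUE, "event"))))
  add(.syn("pos-passive-agent-nominal", pc, "verb", list(
    controlled = ctrl(">nsubj:pass"),
    controller = ctrl(">obl:by >compound|nmod:of?"))))
  add(.syn("pos-nominal-of-by-appos", pc, "noun", list(
    controlled = ctrl(">nmod:of >appos?"),
    controller = ctrl(">nmod:by >appos?"))))
  add(.sur("pos-sur-declarative", pc, "E:controller T E:controlled"))
  add(.sur("pos-sur-nominal-of-by", pc, "T W:of E:controlled W:by E:controller"))
  add(.sur("pos-sur-compound-by", pc, "E:controlled T W:by E:controller"))
  add(.sur("pos-sur-mediated", pc, "E:controller W:- W:mediated T"))

  # --- negative regulation / activation: 14 syntax, 3 surface --------------
  nc <- "negative_regulation_activation"
  add(.syn("neg-declarative", nc, "verb", list(
    controller = ctrl(">nsubj >compound|nmod:of?"),
    controlled = ctrl(">obj|dobj"))))
  add(.syn("neg-declarative-prep", nc, "verb", list(
    controller = ctrl(">nsubj >compound|nmod:of?"),
    controlled = ctrl(">obl:in|obl:to|nmod:in|nmod:to"))))
  add(.syn("neg-passive", nc, "verb", list(
    controlled = ctrl(">nsubj:pass"), controller = ctrl(">obl:by|nmod:by"))))
  add(.syn("neg-nominal-of-by", nc, "noun", list(
    controlled = ctrl(">nmod:of"), controller = ctrl(">nmod:by"))))
  add(.syn("neg-nominal-compound-of", nc, "noun", list(
    controller = ctrl(">compound"), controlled = ctrl(">nmod:of"))))
  add(.syn("neg-nominal-obj-compound", nc, "noun", list(
    controlled = ctrl(">compound"), controller = ctrl(">nmod:by"))))
  add(.syn("neg-subj-relative", nc, "verb", list(
    controller = ctrl("<xcomp? <acl:relcl"), controlled = ctrl(">obj|dobj"))))
  add(.syn("neg-obj-relative", nc, "verb", list(
    controlled = ctrl("<acl:relcl"), controller = ctrl(">obl:by|nmod:by")),
    forbid = ">nsubj"))
  add(.syn("neg-subj-appos", nc, "verb", list(
    controller = ctrl(">nsubj >appos"), controlled = ctrl(">obj|dobj"))))
  add(.syn("neg-obj-appos", nc, "verb", list(
    controller = ctrl(">nsubj"), controlled = ctrl(">obj|dobj >appos"))))
  add(.syn("neg-passive-obl-in", nc, "verb", list(
    controlled = ctrl(">nsubj:pass >compound?"),
    controller = ctrl(">obl:in|nmod:in >compound?"))))
  add(.syn("neg-nominal-poss", nc, "noun", list(
    controller = ctrl(">nmod:poss"), controlled = ctrl(">nmod:of"))))
  add(.syn("neg-passive-agent-nominal", nc, "verb", list(
    controlled = ctrl(">nsubj:pass"),
    controller = ctrl(">obl:by >compound|nmod:of?"))))
  add(.syn("neg-nominal-of-by-appos", nc, "noun", list(
    controlled = ctrl(">nmod:of >appos?"),
    controller = ctrl(">nmod:by >appos?"))))
  add(.sur("neg-sur-declarative", nc, "E:controller T E:controlled"))
  add(.sur("neg-sur-nominal-of-by", nc, "T W:of E:controlled W:by E:controller"))
  add(.sur("neg-sur-compound-by", nc, "E:controlled T W:by E:controller"))

  g
}

.grammar_cache <- new.env(parent = emptyenv())

#' The shipped default grammar (154 rule templates)
#'
#' @return List of `ls_template` covering all 10 categories; the inventory
#'   (see [grammar_inventory()]) is 95 syntax + 59 surface templates, 32 on
#'   the entity side and 122 on the event side.
#' @export
default_grammar <- function() {
  if (is.null(.grammar_cache$g)) .grammar_cache$g <- default_grammar_build()
  .grammar_cache$g
}
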