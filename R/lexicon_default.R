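#' Build the default concept lexicon
#'
#' A 64-concept lexicon spanning the clusters that dominate feature
#' importance in note-based suicide-attempt classification: suicidality
#' findings (including C0424000, "Feeling suicidal (finding)"), family
#' relations, psychiatric disorders, psychotropic and analgesic medications,
#' and care-context / protective concepts. CUI codes are treated as opaque
#' identifiers in the `C#######` code space.
#'
#' @return A `cui_lexicon` with one row per (cui, variant).
#' @export
build_default_lexicon <- function() {
  e <- function(cui, preferred, ...) {
    v <- c(...)
    data.frame(cui = cui, preferred_term = preferred, variant = v,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    # -- suicidality cluster (generator default signal concepts) --
    e("C0424000", "Feeling suicidal (finding)", "feeling suicidal"),
    e("C0038663", "Suicide attempt", "suicide attempt", "suicide attempts",
      "attempted suicide"),
    e("C0038661", "Suicidal ideation", "suicidal ideation",
      "thoughts of suicide", "suicidal thoughts"),
    e("C0344315", "Depressed mood", "depressed mood", "low mood"),
    e("C0588008", "Severe depression", "severe depression"),
    e("C0018592", "Hopelessness", "hopelessness", "feels hopeless"),
    e("C0085633", "Self-injurious behavior", "self harm", "self injury",
      "cutting behavior"),
    e("C0030193", "Pain", "pain"),
    e("C0086133", "Drug overdose", "overdose", "took an overdose"),
    e("C0455204", "Risk to self", "risk to self", "safety concerns"),
    # -- family relations --
    e("C0015671", "Father", "father", "fathers"),
    e("C0337527", "Brother", "brother", "brothers"),
    e("C0337570", "Grandfather", "grandfather"),
    e("C0030551", "Parent", "parent", "parents"),
    e("C0037047", "Sibling", "sibling", "siblings"),
    e("C0026591", "Mother", "mother", "mothers"),
    e("C0337514", "Sister", "sister", "sisters"),
    # -- psychiatric disorders and behaviors --
    e("C0038436", "Post-traumatic stress disorder", "ptsd",
      "post traumatic stress disorder"),
    e("C0033975", "Psychotic disorder", "psychosis", "unspecified psychosis"),
    e("C0005586", "Bipolar disorder", "bipolar", "bipolar disorder"),
    e("C1263846", "Attention deficit hyperactivity disorder", "adhd",
      "attention deficit hyperactivity disorder"),
    e("C0038586", "Substance use disorder", "substance use", "substance abuse"),
    e("C0003469", "Anxiety disorder", "anxiety", "anxiety disorder"),
    e("C0011570", "Major depressive disorder", "major depression",
      "major depressive disorder"),
    e("C0030319", "Panic attack", "panic attack", "panic attacks"),
    e("C0013473", "Eating disorder", "eating disorder", "disordered eating"),
    e("C0917801", "Insomnia", "insomnia", "trouble sleeping"),
    e("C0001948", "Alcohol use", "alcohol use", "drinking alcohol"),
    e("C0007642", "Cannabis use", "cannabis use", "marijuana use"),
    e("C0040822", "History of trauma", "trauma history", "history of trauma"),
    e("C0019337", "Aggressive behavior", "aggression", "aggressive behavior"),
    e("C0021123", "Impulsivity", "impulsivity", "impulsive behavior"),
    # -- medications --
    e("C0016365", "Fluoxetine", "fluoxetine", "prozac"),
    e("C0074393", "Sertraline", "sertraline", "zoloft"),
    e("C0065374", "Lorazepam", "lorazepam", "ativan"),
    e("C0073393", "Risperidone", "risperidone", "risperdal"),
    e("C0123091", "Quetiapine", "quetiapine", "seroquel"),
    e("C0023870", "Lithium", "lithium"),
    e("C0020740", "Ibuprofen", "ibuprofen"),
    e("C0000970", "Acetaminophen", "acetaminophen", "tylenol"),
    e("C0008845", "Citalopram", "citalopram", "celexa"),
    e("C0025219", "Melatonin", "melatonin"),
    e("C0009014", "Clonidine", "clonidine"),
    e("C0282606", "Antidepressant agent", "antidepressant", "antidepressants"),
    # -- care context and protective concepts --
    e("C0085092", "Family conflict", "family conflict", "conflict at home"),
    e("C0042798", "Family support", "family support", "supportive family"),
    e("C0036588", "Social support", "social support"),
    e("C0150600", "Safety plan", "safety plan", "safety planning"),
    e("C0009244", "Coping skills", "coping skills", "coping strategies"),
    e("C0033968", "Psychotherapy", "therapy", "psychotherapy", "counseling"),
    e("C0036372", "School engagement", "school engagement", "engaged at school"),
    e("C0242271", "Academic achievement", "academic achievement", "good grades"),
    e("C0679646", "Peer support", "peer support", "close friends"),
    e("C0035036", "Religious involvement", "religious involvement",
      "attends church"),
    e("C0036709", "Social isolation", "social isolation", "socially isolated"),
    e("C0006157", "Bullying", "bullying", "bullied at school"),
    e("C0150055", "Medication adherence", "medication adherence",
      "taking medications as prescribed"),
    e("C0242802", "Medication noncompliance", "medication noncompliance",
      "not taking medications"),
    e("C0018684", "Psychiatric hospitalization", "prior hospitalization",
      "psychiatric hospitalization"),
    e("C0242428", "Runaway behavior", "running away", "ran away from home"),
    e("C0016452", "Foster care", "foster care"),
    e("C0376558", "Future orientation", "future plans", "future orientation"),
    e("C0237284", "Exercise", "exercise", "exercise routine"),
    e("C0020872", "Hobbies", "hobbies")
  )
  cui_lexicon(rows)
}

#' Default signal concepts for the synthetic-corpus generator
#'
#' The ten suicidality-cluster CUIs whose per-note mention rates differ by
#' patient label in the default generator configuration.
#'
#' @return Character vector of ten CUI codes.
#' @keywords internal
default_signal_cuis <- function() {
  c("C0424000", "C0038663", "C0038661", "C0344315", "C0588008",
    "C0018592", "C0085633", "C0030193", "C0086133", "C0455204")
}
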