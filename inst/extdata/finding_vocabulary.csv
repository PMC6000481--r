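category,term
pain_paresthesia,burning
pain_paresthesia,cold
pain_paresthesia,cramping
pain_paresthesia,dull
pain_paresthesia,electric
pain_paresthesia,heavy
pain_paresthesia,hot
pain_paresthesia,numb
pain_paresthesia,pressing
pain_paresthesia,pricking
pain_paresthesia,radiating
pain_paresthesia,shooting
pain_paresthesia,stabbing
pain_paresthesia,tender
pain_paresthesia,throbbing
pain_paresthesia,tingling
pain_paresthesia,tugging
skin_sensitivity,allodynia
skin_sensitivity,analgesia
skin_sensitivity,anesthesia
skin_sensitivity,dysesthesia
skin_sensitivity,hypoesthesia
skin_sensitivity,hyperalgesia
skin_sensitivity,hypoalgesia
skin_sensitivity,pallanesthesia
skin_sensitivity,pallhypesthesia
skin_sensitivity,thermanesthesia
skin_sensitivity,thermhypesthesia
skin_perfusion,cyanosis
skin_perfusion,hyperthermia
skin_perfusion,hypothermia
skin_perfusion,pallor
skin_perfusion,redness
skin_perfusion,swelling
skin_autonomic,anhidrosis
skin_autonomic,atrophy
skin_autonomic,hyperhidrosis
skin_autonomic,hypertrophy
skin_autonomic,piloerection
muscle,allodynia
muscle,atrophy
muscle,disturbed proprioception
muscle,fasciculation
muscle,hyperalgesia
muscle,hypotonia
muscle,muscular defense
muscle,myogelosis
muscle,rebound tenderness
muscle,rigor
muscle,spasm
muscle,tenderness
organ,tenderness
organ,hypertrophy
organ,induration
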