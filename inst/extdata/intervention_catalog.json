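{"interventions":[{"availability":"proximity_to_practice","category":"group_based","description":"Group mindfulness training to prevent and reduce stress.","id":"mindfulness-group","name":"Mindfulness group course","target_parameter_ids":["perceived_stress","mental_health"]},{"availability":"within_municipality","category":"group_based","description":"Weekly group walks combining exercise and social contact.","id":"walking-club","name":"Neighborhood walking club","target_parameter_ids":["physical_activity","loneliness"]},{"availability":"within_municipality","category":"group_based","description":"Guided group program for smoking cessation.","id":"quit-smoking-group","name":"Stop-smoking group training","target_parameter_ids":["smoking"]},{"availability":"proximity_to_practice","category":"group_based","description":"Hands-on workshop on diabetes-friendly meals.","id":"cooking-workshop","name":"Healthy cooking workshop","target_parameter_ids":["eating_pattern"]},{"availability":"within_municipality","category":"events","description":"Informal meet-up for people with diabetes.","id":"diabetes-cafe","name":"Diabetes cafe","target_parameter_ids":["problems_with_diabetes","loneliness"]},{"availability":"within_municipality","category":"events","description":"Local event with lifestyle information stands.","id":"health-market-day","name":"Health market day","target_parameter_ids":["eating_pattern","physical_activity"]},{"availability":"proximity_to_practice","category":"events","description":"Try-out sessions of local sports clubs.","id":"sports-taster-day","name":"Neighborhood sports taster day","target_parameter_ids":["physical_activity"]},{"availability":"proximity_to_practice","category":"experts_knowledge_centers","description":"Individual dietary counselling.","id":"dietician-referral","name":"Referral to a dietician","target_parameter_ids":["eating_pattern","weight","cholesterol","glucose_metabolism"]},{"availability":"proximity_to_practice","category":"experts_knowledge_centers","description":"Supervised exercise therapy.","id":"physio-referral","name":"Referral to a physiotherapist","target_parameter_ids":["physical_activity","pain"]},{"availability":"proximity_to_practice","category":"experts_knowledge_centers","description":"Short psychological support in the practice.","id":"mental-health-nurse","name":"Practice mental-health nurse","target_parameter_ids":["mental_health","perceived_stress"]},{"availability":"within_municipality","category":"experts_knowledge_centers","description":"Help with money, work, housing and family problems.","id":"social-work-referral","name":"Referral to social work","target_parameter_ids":["income","work","housing","family"]},{"availability":"nationwide_web","category":"experts_knowledge_centers","description":"Structured diabetes self-management education.","id":"diabetes-education-center","name":"Diabetes education center","target_parameter_ids":["problems_with_diabetes","diabetes_management","perceived_health"]},{"availability":"nationwide_web","category":"apps","description":"Log and review blood-sugar values.","id":"glucose-diary-app","name":"Glucose diary app","target_parameter_ids":["diabetes_management","glucose_metabolism"]},{"availability":"nationwide_web","category":"apps","description":"Counts daily steps and nudges movement breaks.","id":"step-counter-app","name":"Step counter app","target_parameter_ids":["physical_activity","sedentary_behavior"]},{"availability":"nationwide_web","category":"apps","description":"Guided relaxation and breathing exercises.","id":"mindfulness-app","name":"Mindfulness app","target_parameter_ids":["perceived_stress","mental_health"]},{"availability":"nationwide_web","category":"apps","description":"Tracks meals against dietary guidelines.","id":"food-diary-app","name":"Food diary app","target_parameter_ids":["eating_pattern","weight"]},{"availability":"nationwide_web","category":"apps","description":"Self-monitoring of alcohol consumption.","id":"drink-less-app","name":"Drink-less app","target_parameter_ids":["alcohol"]},{"availability":"nationwide_web","category":"apps","description":"Digital coach for smoking cessation.","id":"quit-smoking-app","name":"Quit-smoking app","target_parameter_ids":["smoking"]},{"availability":"nationwide_web","category":"devices","description":"Wearable pedometer.","id":"step-counter-device","name":"Step counter","target_parameter_ids":["physical_activity"]},{"availability":"nationwide_web","category":"devices","description":"Heart-rate monitor for safe exercising.","id":"pulse-meter","name":"Pulse meter","target_parameter_ids":["physical_activity"]},{"availability":"nationwide_web","category":"devices","description":"Self-measurement of blood pressure at home.","id":"home-bp-monitor","name":"Home blood-pressure monitor","target_parameter_ids":["blood_pressure"]},{"availability":"within_municipality","category":"programs","description":"Two-year program combining diet, exercise and coaching.","id":"combined-lifestyle-program","name":"Combined lifestyle intervention","target_parameter_ids":["weight","eating_pattern","physical_activity"]},{"availability":"proximity_to_practice","category":"programs","description":"Structured follow-up of cardiovascular risk factors.","id":"cvrm-program","name":"Cardiovascular risk management program","target_parameter_ids":["blood_pressure","cholesterol"]},{"availability":"nationwide_web","category":"programs","description":"Online program on relaxation and sleep.","id":"sleep-stress-program","name":"Sleep and stress program","target_parameter_ids":["perceived_stress","mental_health"]},{"availability":"nationwide_web","category":"knowledge_platforms","description":"Evidence-based dietary information.","id":"nutrition-platform","name":"National nutrition platform","target_parameter_ids":["eating_pattern"]},{"availability":"nationwide_web","category":"knowledge_platforms","description":"Peer stories and self-management knowledge.","id":"diabetes-platform","name":"Diabetes association platform","target_parameter_ids":["problems_with_diabetes","diabetes_management"]},{"availability":"nationwide_web","category":"knowledge_platforms","description":"Information on protecting kidney function.","id":"kidney-platform","name":"Kidney health platform","target_parameter_ids":["kidney_function"]}],"note":"Synthetic example catalog; entries are category-faithful stand-ins, not real programs.","schema_id":"diag360/catalog","schema_version":"1.0"}
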