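{"cards":[{"examples":[],"goal":"","index":1,"kind":"front_matter","parts":[],"title":"title page"},{"examples":[],"goal":"","index":2,"kind":"front_matter","parts":["Overview of the cards in this deck."],"title":"content"},{"examples":["Ask permission before giving information.","Let the patient set the pace."],"goal":"Adopt a collaborative, accepting and compassionate stance that evokes the patient's own motivation.","index":3,"kind":"mi_skill","parts":["Partnership","Acceptance","Compassion","Evocation"],"title":"MI basic attitude"},{"examples":["What would you like to talk about today?","What makes this important to you?"],"goal":"Use open questions to explore the patient's perspective.","index":4,"kind":"mi_skill","parts":["Open questions","Avoiding the question-answer trap"],"title":"MI core skills 1"},{"examples":["You have already managed to cut down once before.","So mornings are the hardest moment for you."],"goal":"Use affirmations and reflective listening to support change talk.","index":5,"kind":"mi_skill","parts":["Affirmations","Simple and complex reflections"],"title":"MI core skills 2"},{"examples":["Let me pull together what you said so far.","Would it be okay if I share what the guideline advises?"],"goal":"Summarize and exchange information with permission.","index":6,"kind":"mi_skill","parts":["Summaries","Elicit-provide-elicit"],"title":"MI core skills 3"},{"examples":[],"goal":"","index":7,"kind":"front_matter","parts":["Step 1 agenda","Step 2 current situation","Step 3 motivation","Step 4 planning","Step 5 rounding up"],"title":"diabetes coaching steps overview"},{"examples":["Which of the orange or red icons would you like to discuss first?"],"goal":"Set the agenda together using the profile wheel.","index":8,"kind":"step","parts":["Review the wheel","Let the patient pick topics","Agree on the focus of today"],"step_number":1,"title":"step 1 agenda"},{"examples":["Tell me about a normal day with your diabetes."],"goal":"Explore the current situation behind the chosen parameter.","index":9,"kind":"step","parts":["Open exploration","Day-to-day impact"],"step_number":2,"title":"step 2 current situation I"},{"examples":["What has helped you before, even a little?"],"goal":"Deepen understanding of barriers and resources.","index":10,"kind":"step","parts":["Barriers","Earlier attempts","Support network"],"step_number":2,"title":"step 2 current situation II"},{"examples":["On a scale of 0 to 10, how important is this change for you?"],"goal":"Elicit and strengthen the patient's own reasons for change.","index":11,"kind":"step","parts":["Change talk","Importance ruler"],"step_number":3,"title":"step 3 motivation I"},{"examples":["What would make you move from a 4 to a 6 in confidence?"],"goal":"Explore ambivalence and confidence.","index":12,"kind":"step","parts":["Pros and cons","Confidence ruler"],"step_number":3,"title":"step 3 motivation II"},{"examples":["Which of these options feels like the best fit for you?"],"goal":"Translate motivation into a concrete, patient-owned goal.","index":13,"kind":"step","parts":["Goal setting","Options from the intervention overview"],"step_number":4,"title":"step 4 planning I"},{"examples":["If the weather is bad, what will you do instead of the walk?"],"goal":"Make the plan specific and anticipate obstacles.","index":14,"kind":"step","parts":["When-where-how","If-then planning"],"step_number":4,"title":"step 4 planning II"},{"examples":["So you will join the walking club twice a week, and we meet again in 3 months."],"goal":"Choose an intervention for one orange or red parameter and summarize the plan.","index":15,"kind":"step","parts":["Choose the intervention","Summarize","Plan the follow-up after about 3 months"],"step_number":5,"summary_fields":["current situation","goal parameter","chosen intervention","backup plans","resources"],"title":"step 5 rounding up"}],"note":"Card bodies are paraphrased placeholders keyed to the printed titles; full card prose is not public.","schema_id":"diag360/card-deck","schema_version":"1.0"}
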